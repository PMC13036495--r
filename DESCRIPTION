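Package: filamech
Title: Mechanics and Assembly Kinetics of Nucleoprotein Filaments from
    Magnetic-Tweezers Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-molecule magnetic-tweezers time traces of
    protein filaments assembling on double-stranded RNA tethers.  Fits the
    inextensible worm-like chain model to force-extension data through an
    integrated-energy transform, extracts filament nucleation, formation and
    ATP-driven compaction rates from constant-force traces with sliding-window
    slope estimators, detects abrupt rupture events, classifies trace outcomes,
    converts persistence lengths to fractional lattice occupancy and fits a
    Hill binding model with bootstrap uncertainties.  A seeded stochastic trace
    generator emulates the experiment (Brownian extension noise, exponential
    nucleation, cooperative linear growth, compaction with ruptures, force
    ramps and rotation-extension sweeps) so every estimator has a
    parameter-recovery test surface without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
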
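# filamech

Analysis of single-molecule magnetic-tweezers traces of protein filaments
assembling on dsRNA tethers — written for biophysicists who need to turn
bead time series into mechanics and kinetics: worm-like chain (WLC)
parameters, filament nucleation/growth/compaction rates, rupture events,
trace outcome classes, and cooperative-binding constants.

The motivating system is the innate-immune receptor MDA5, which
polymerizes into stiff filaments on long double-stranded RNA and, upon ATP
hydrolysis, compacts the nucleoprotein complex; but every stage is generic
to nucleoprotein-filament tweezers experiments.

## What it computes

**Mechanics.** The inextensible WLC force law

    F(L) = (kBT/Lp) * [ 1/(4 (1 - L/Lc)^2) - 1/4 + L/Lc ]

is fitted to dynamic force–extension curves in the *energy domain*: the
measured trace is integrated (trapezoid over extension-sorted, 1-s-averaged
samples) and matched to the closed-form integral of the force law, which
suppresses Brownian position noise. Fits are screened against the window
0 ≤ Lp ≤ 500 nm, 700 ≤ Lc ≤ 2000 nm.

**Kinetics.** Constant-force traces are segmented (baseline → nucleation →
growth → compaction → floor); rates come from least-squares slopes in
sliding windows (20 s for formation, 50 s for compaction, 0.1 nm/s
detection limit), growth rates are normalized to monomers/s via the 14 bp
monomer footprint on the 3149 bp lattice, rupture jumps are counted by a
2-sigma/5-s rule, and traces are classified as fully compacted / partially
compacted / dissociated / extended.

**Binding.** Persistence lengths map to fractional occupancy through a
square-root normalization, and the Hill isotherm
alpha(c) = c^n / (KD^n + c^n) is fitted by weighted nonlinear least
squares with a 1000-sample case bootstrap.

**Synthetic data.** A seeded generator produces assembly, compaction,
force-ramp, rotation–extension and occupancy cohorts with known ground
truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(filamech)

## bare dsRNA stretches to ~47% of its contour length at 0.1 pN
p <- wlc_params(lp = 45, lc = 896)
invert_wlc(0.1, p) / p$lc
#> [1] 0.4665078

## recover mechanics from a noisy simulated force ramp
tr  <- simulate_force_ramp(sim_config(duration = 40, seed = 101), p,
                           noise_sd = 30)
fit <- fit_wlc_integrated(data.frame(extension = tr$extension,
                                     force = tr$force))
fit
#> WLC fit: Lp = 43.57 nm, Lc = 898.41 nm (accepted)

## an assembly trace at the saturating-concentration kinetics
tru <- ground_truth()        # 0.062 1/s nucleation, 8 monomers/s growth
tr  <- simulate_assembly_trace(sim_config(duration = 150, flush_time = 20,
                                          seed = 7), tru)
detect_nucleation(tr)        # waiting time after the flush, s
#> [1] 2
reg   <- propose_regions(tr)
delta <- invert_wlc(0.1, wlc_params(200, 896)) - invert_wlc(0.1, p)
monomer_rate(formation_rate(tr, reg$formation), delta)
#> [1] 8.060297

## cooperative binding from a binomial occupancy cohort
pts <- simulate_occupancy_counts(c(25, 50, 100, 150, 200, 300),
                                 kd = 25, n = 1.8, n_all = 50, seed = 42)
hill_fit(pts, n_boot = 1000)
#> Hill fit (1000 bootstrap samples): KD = 27.2 +/- 11 nM, n = 1.98 +/- 0.57
```

The first number says bare dsRNA at 0.1 pN sits near half its contour
length (why that force maximizes the extension change on filament
formation); the fit recovers the generator's mechanics from 30 nm of
Brownian noise; the kinetics block reads a nucleation waiting time and a
growth rate in monomers/s off a synthetic trace; the Hill fit returns the
dissociation constant and cooperativity with bootstrap uncertainties.

A methods vignette (`vignettes/filament-mechanics.Rmd`) documents the
models, thresholds, design decisions and limitations. A thin CLI wrapper
lives in `inst/cli/filamech.R` (verbs `simulate`, `fit-wlc`,
`analyze-trace`, `hill`).

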
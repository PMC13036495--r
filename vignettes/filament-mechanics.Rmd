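---
title: "Filament mechanics and kinetics from magnetic-tweezers traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filament mechanics and kinetics from magnetic-tweezers traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamech)
```

## The measurement and the model

A magnetic-tweezers experiment tracks the end-to-end extension of a single
nucleic-acid tether (here a ~3.2 kbp, 3149 bp dsRNA) held under calibrated
force between a glass surface and a magnetic bead, sampled at 58 Hz. When a
filament-forming protein such as the innate-immune receptor MDA5 is flushed
into the cell, the trace runs through distinct phases: a bare-tether
baseline, a stochastic nucleation waiting time, a roughly linear extension
increase as the filament grows cooperatively along the lattice, and — once
ATP hydrolysis is allowed — a compaction phase in which the extension falls
steadily, punctuated by abrupt upward "rupture" jumps, until the complex
locks into a tight floor state with visibly reduced Brownian fluctuation.

`filamech` implements the full quantitative chain from such traces to
biophysical parameters, plus a seeded generator of synthetic traces with the
same statistical structure, so that every estimator can be validated by
parameter recovery without instrument data.

## Tether mechanics: the worm-like chain in the energy domain

The mechanics core is the inextensible worm-like chain (WLC)
interpolation formula,

$$F(L) = \frac{k_B T}{L_p}\left[\frac{1}{4\,(1 - L/L_c)^2} - \frac{1}{4}
  + \frac{L}{L_c}\right],$$

with persistence length $L_p$ (45 nm for bare dsRNA, rising roughly
four-fold to ~200 nm for the complete filament), contour length $L_c$
(~896 nm) and $k_BT$ fixed at 4.11 pN nm (25 °C) throughout the package —
a single constant avoids hidden unit bugs. At 0.1 pN, the force used for
assembly experiments, this model puts bare dsRNA at about 47% of its
contour length:

```{r}
p <- wlc_params(lp = 45, lc = 896)
invert_wlc(0.1, p) / p$lc
```

Raw force–extension samples are dominated by Brownian bead motion, so the
package fits in the *energy domain*: the closed-form integral of the force
law,

$$E(L) = \int_0^{L} F\,dL' = \frac{1}{4}\,
  \frac{k_B T\, L^2\,(2L - 3L_c)}{L_p L_c (L - L_c)},$$

is matched against the trapezoid-accumulated measured energy
$\int F\,d L_{\mathrm{ext}}$ over the extension-sorted samples.
`fit_wlc_integrated()` flags results against the acceptance window
$0 \le L_p \le 500$ nm, $700 \le L_c \le 2000$ nm; out-of-window fits are
retained with `accepted = FALSE` — the window is a filter, not a constraint.
Replicate curves are fitted individually and summarized as mean ± sd of the
accepted parameters.

Two numerical choices matter here and were genuinely open:

* **Pre-averaging.** Both channels are smoothed with the experiment's
  standard 58-frame (1 s) moving average, in acquisition order, before the
  extension sort and integration (`smooth_window`, set 1 to disable).
  Sorting raw samples with tens of nanometers of extension noise convolves
  the steep near-contour rise of the curve and attenuates the recovered
  stiffness severely (we measured a ~60% downward bias in $L_p$ at 30 nm
  noise); averaging over the slow magnet motion removes this at negligible
  cost in resolution.
* **Offset anchoring.** The measured integral starts at the smallest
  sampled extension, not zero. Modelling that with a free additive offset
  makes very large $L_c$ degenerate (the model flattens into an
  $L_pL_c$-only family); the model is instead referenced analytically to
  the smallest sampled extension.

A property test confirms the motivation for the transform: at 50 nm
extension noise the energy-domain fit beats a direct least-squares fit of
the force law by an order of magnitude in $L_p$ RMSE.

## Kinetics: segmentation, sliding-window slopes, ruptures, classes

All kinetic estimators operate on the 1 Hz moving-average view of the raw
trace, as in the experiment.

* **Nucleation** (`detect_nucleation`): the first post-flush instant where
  the filtered extension exceeds the pre-flush baseline mean by 3 baseline
  standard deviations and stays above for at least 10 s. The threshold and
  dwell are configurable; they are a reproducible surrogate for a manual
  call, so the defaults were chosen once for a clear separation between
  Brownian excursions and genuine growth at the package's default noise.
  Detection necessarily lags the true crossing by the time growth needs to
  climb the threshold (~1 s at default settings); at the population level
  this biases the nucleation rate a few percent low, well within the
  recovery tolerances used in the tests.
* **Formation** (`formation_rate`): ordinary least-squares slopes in 20 s
  sliding windows advanced one 1-Hz sample at a time; windows whose net
  extension increase fails twice the baseline dispersion are discarded; the
  mean surviving slope is reported. The source procedure words the
  threshold as "twice the variance", which is dimensionally inconsistent
  (nm² against nm); the package uses twice the baseline *standard
  deviation* by default and exposes `threshold_mode = "variance"` for the
  literal reading.
* **Footprint normalization** (`monomer_rate`): slopes in nm/s divide by
  the extension gained per bound monomer,
  $\Delta L_{\mathrm{ext}} \cdot 14\,\mathrm{bp} / 3149\,\mathrm{bp}$,
  where $\Delta L_{\mathrm{ext}}$ is the full-filament extension change at
  the working force.
* **Compaction** (`compaction_rate`): the same construction with 50 s
  windows, keeping negative slopes only, reported as positive magnitudes,
  with slopes below the 0.1 nm/s detection limit excluded — below-detection
  outcomes are returned as `NA` and counted, never silently zeroed.
  Windows overlapping a supplied rupture time are discarded: a single
  ~50 nm upward jump contaminates every 50 s window that contains it, which
  would otherwise bias a 5 nm/s estimate by well over the recovery
  tolerance; masking detected ruptures restores an unbiased estimate from
  the clean stretches.
* **Ruptures** (`detect_ruptures`): an event is counted whenever the 1 Hz
  signal rises by more than twice the pre-ATP raw standard deviation within
  any 5 s window; crossings closer than 5 s merge into one event.
* **Classification** (`classify_trace`): `fully_compacted` (ends at the
  compacted floor and any post-run force–extension fit shows no compliant
  response), `partially_compacted` (below the bare extension, no stable
  floor), `dissociated` (decreased, never below bare), `extended` (only
  increased, stable). Traces firing none of the rules become
  `unclassified` — a deliberate extension so that ambiguity is counted
  rather than forced.
* **Regions** (`propose_regions`): formation from the nucleation crossing
  to 95% of the net rise; compaction from the filtered maximum to within
  noise of the final level. This is the reproducible surrogate for manual
  region selection; both estimators also accept explicit regions.

## Binding: occupancy normalization and the bootstrap Hill fit

Fractional occupancy is inferred from persistence lengths through the
square-root normalization

$$\alpha = \frac{\sqrt{1/L_{p,i}} - \sqrt{1/\bar L_p}}
  {\sqrt{1/L_{p,\mathrm{full}}} - \sqrt{1/\bar L_p}},$$

where $\bar L_p$ is interpreted as the mean *bare-tether* persistence
length — the natural $\alpha = 0$ anchor — and the saturating-concentration
filament supplies $\alpha = 1$. Noisy inputs may leave $[0,1]$ and are
returned unclamped with a flag; clamping would bias the fit near the
boundaries. The same map, inverted, is what the simulator uses to convert
coverage to stiffness (`coverage_lp`), so generator and estimator are
self-consistent by construction.

`hill_fit()` weights each occupancy point by its inverse squared binomial
error $\delta f = \sqrt{f(1-f)/N}$ and fits
$\alpha(c) = c^n/(K_D^n + c^n)$ by Levenberg–Marquardt in log-parameter
space (a hard $K_D$ bound produces singular Jacobians on near-saturated
bootstrap resamples; the log parameterization keeps those refits smooth).
Case resampling with replacement, 1000 draws by default, yields the
bootstrap mean as point estimate and the bootstrap sd as uncertainty; a fit
fails loudly when more than 20% of refits do not converge. Zero binomial
errors at observed fractions of 0 or 1 understate the real uncertainty, so
weights are floored at half the smallest positive uncertainty among the
points. With the saturating concentration design used in the experiments
(lowest concentration at $K_D$, no low-occupancy flank), the Hill
coefficient is weakly constrained and its bootstrap-mean estimate scatters
substantially between cohorts — the package reports that scatter honestly
as `n_sd` rather than narrowing it.

## The synthetic generator

The generator emulates exactly the statistical structure the estimators
assume: exponential nucleation waiting times per lattice segment,
continuous linear coverage growth (single 14 bp steps are far below the nm
extension resolution), extension from the WLC inversion at a
coverage-dependent persistence length, Poisson rupture arrivals with
Gaussian jump sizes, Normal rupture forces on high-force ramps, linear
turn–extension responses, and per-sample Gaussian extension noise with a
$\sqrt{0.1\,\mathrm{pN}/F}$ force scaling (default 20 nm at 0.1 pN) —
stand-ins chosen once to match the visible raw-trace envelopes, exposed in
the configuration. The compacted floor defaults to 10% of the contour
length with noise scaled by 0.2, emulating the reduced bead-height
fluctuation of the locked complex without a structural model. Force ramps
are generated directly as log-linear force profiles; magnet-physics force
calibration is out of scope.

What the generator deliberately does *not* model: Langevin bead dynamics,
camera blur or tracking noise, magnet-field physics, discrete lattice
stepping, heterogeneous protein batches. Passing recovery tests therefore
demonstrate estimator correctness under the stated stochastic model, not
robustness to every instrumental artifact of real data.

Determinism is part of the contract: identical configuration and seed give
bit-identical traces, and cohort seeds derive from a root seed.

## Problem sizes and tolerances used in the checks

The validation suite recovers, from cohorts generated at the study's
reported values: contour length (20 ramps, 30 nm noise, within 5%) and
persistence lengths (within 15%); nucleation rate 0.062 s⁻¹ (200 traces,
within 15%); formation rate 8 monomers/s (50 traces, within 20%);
compaction rate 5 nm/s with ~2 ruptures per trace (50 traces, within 15%);
and the binding parameters $K_D = 25$ nM, $n = 1.8$ (noiseless within 1%;
binomial cohorts covered by the fit's own 2-sd bootstrap interval in at
least 90% of seeds, with the bootstrap reduced to 200 draws for the
many-seed sweep). Analytic identities (energy ≡ quadrature of the force
law at 10⁻⁸ relative; Hill midpoint; occupancy endpoints; binomial-error
boundary and maximum) are property-tested over random parameters.

## Known limitations

* Thresholded segmentation only — no changepoint models or HMMs, matching
  the analysis being reproduced.
* The nucleation dwell rule cannot distinguish very slow growth from a
  late nucleus near the end of a trace.
* The Hill coefficient is poorly identified by saturating designs (see
  above); confidence comes from the bootstrap spread, not the point value.
* `extract_rupture_forces` picks the single largest jump per ramp;
  multi-rupture staircases on one ramp report only the dominant event.
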
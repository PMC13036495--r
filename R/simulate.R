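# Seeded stochastic generator of magnetic-tweezers traces: constant-force
# filament assembly, ATP-driven compaction with rupture events, force ramps
# and rotation-extension sweeps, plus binomial occupancy cohorts.  Every
# generator sets the RNG from config$seed so identical inputs give
# bit-identical traces.

#' Simulation protocol configuration
#'
#' @param duration Trace duration in s.
#' @param sample_rate Acquisition frequency in Hz (default 58).
#' @param force Applied force in pN (constant-force protocols).
#' @param noise_sd Extension noise standard deviation in nm of the raw signal
#'   at the 0.1 pN reference force.  At other forces the per-sample Gaussian
#'   noise scales as `noise_sd * sqrt(0.1 / F)` (larger Brownian fluctuations
#'   at low force).
#' @param flush_time Time in s at which protein reaches the tether; the trace
#'   before it is the bare-tether baseline.
#' @param seed Integer random seed.
#'
#' @return A `sim_config` object.
#' @export
sim_config <- function(duration, sample_rate = 58, force = 0.1,
                       noise_sd = 20, flush_time = 0, seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (flush_time < 0 || flush_time >= duration)
    stop("flush_time must lie in [0, duration)")
  structure(list(duration = duration, sample_rate = sample_rate,
                 force = force, noise_sd = noise_sd,
                 flush_time = flush_time, seed = as.integer(seed)),
            class = "sim_config")
}

#' Ground-truth parameters of a simulated filament experiment
#'
#' Defaults are the regime of a cooperative helicase-family filament
#' assembling on a ~3.2 kbp dsRNA tether: 14 bp occluded per monomer on a
#' 3149 bp lattice, bare-tether persistence length 45 nm rising to 200 nm for
#' the complete filament, contour length 896 nm, saturating nucleation rate
#' 0.062 1/s and growth rate 8 monomers/s at high protein concentration,
#' compaction at 5 nm/s, and compacted filaments rupturing at 20 +/- 4 pN.
#'
#' @param k_nucl Nucleation rate in 1/s (exponential waiting times).
#' @param k_form Filament growth rate in monomers/s.
#' @param k_comp Compaction rate in nm/s.
#' @param footprint_bp Base pairs occluded per bound monomer.
#' @param tether_bp Tether lattice length in bp.
#' @param lp_bare,lp_full Persistence lengths (nm) of the bare tether and the
#'   complete filament.
#' @param lc Contour length in nm.
#' @param rupture_rate Rupture events per second during compaction.
#' @param rupture_size_nm Mean abrupt upward extension jump per rupture (nm).
#' @param rupture_force_mean,rupture_force_sd Normal rupture-force sampling
#'   (pN) for high-force ramps on compacted filaments.
#' @param pos_turn_slope,neg_turn_slope Extension drop in nm per added
#'   positive / negative magnet turn for a coilable tether.
#' @param gap_at Optional fraction in (0, 1): position of a single-stranded
#'   gap that filament growth cannot cross, splitting the lattice into two
#'   independently nucleating segments.
#'
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(k_nucl = 0.062, k_form = 8, k_comp = 5,
                         footprint_bp = 14, tether_bp = 3149,
                         lp_bare = 45, lp_full = 200, lc = 896,
                         rupture_rate = 0, rupture_size_nm = 50,
                         rupture_force_mean = 20, rupture_force_sd = 4,
                         pos_turn_slope = 15, neg_turn_slope = 1,
                         gap_at = NULL) {
  if (any(c(k_nucl, k_form, k_comp, rupture_rate) < 0))
    stop("rates must be >= 0")
  if (!(lp_bare > 0 && lp_full >= lp_bare))
    stop("need 0 < lp_bare <= lp_full")
  if (!is.null(gap_at) && (gap_at <= 0 || gap_at >= 1))
    stop("gap_at must lie in (0, 1)")
  structure(list(k_nucl = k_nucl, k_form = k_form, k_comp = k_comp,
                 footprint_bp = footprint_bp, tether_bp = tether_bp,
                 lp_bare = lp_bare, lp_full = lp_full, lc = lc,
                 rupture_rate = rupture_rate,
                 rupture_size_nm = rupture_size_nm,
                 rupture_force_mean = rupture_force_mean,
                 rupture_force_sd = rupture_force_sd,
                 pos_turn_slope = pos_turn_slope,
                 neg_turn_slope = neg_turn_slope,
                 gap_at = gap_at),
            class = "ground_truth")
}

.noise_sd_at <- function(sd0, force) sd0 * sqrt(0.1 / pmax(force, 1e-6))

.new_trace <- function(time, extension, force, turns, metadata) {
  stopifnot(length(extension) == length(time),
            all(diff(time) > 0), all(is.finite(extension)))
  df <- data.frame(time = time, extension = extension,
                   force = rep_len(force, length(time)),
                   turns = rep_len(turns, length(time)))
  structure(df, metadata = metadata, class = c("fm_trace", "data.frame"))
}

#' Trace metadata
#' @param trace An `fm_trace` object.
#' @return The metadata list attached to the trace.
#' @export
trace_meta <- function(trace) attr(trace, "metadata")

#' @export
print.fm_trace <- function(x, ...) {
  md <- trace_meta(x)
  cat(sprintf("Tweezers trace: %d samples, %.1f s at %.3g pN (%s)\n",
              nrow(x), max(x$time) - min(x$time),
              stats::median(x$force),
              if (!is.null(md$protocol)) md$protocol else "unknown protocol"))
  invisible(x)
}

#' Simulate a constant-force filament assembly trace
#'
#' Baseline at the bare-tether WLC extension, a nucleation waiting time drawn
#' from Exp(`k_nucl`) per lattice segment after the protein flush, linear
#' coverage growth at `k_form` monomers/s (capped by the segment capacity
#' `tether_bp / footprint_bp`, and by a single-stranded gap when present),
#' with the instantaneous extension obtained by inverting the WLC force law
#' at a coverage-dependent persistence length ([coverage_lp()]), plus
#' force-scaled Gaussian extension noise.
#'
#' @param config A [sim_config()]; the force protocol must be constant.
#' @param truth A [ground_truth()].
#'
#' @return An `fm_trace` whose metadata records the protocol, flush start,
#'   per-segment nucleation times, growth end and the ground truth.
#' @export
simulate_assembly_trace <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (length(config$force) != 1L)
    stop("assembly protocol requires a constant force")
  set.seed(config$seed)
  dt <- 1 / config$sample_rate
  time <- seq(0, config$duration, by = dt)
  n <- length(time)
  max_monomers <- truth$tether_bp / truth$footprint_bp
  segs <- if (is.null(truth$gap_at)) 1 else c(truth$gap_at, 1 - truth$gap_at)

  monomers <- numeric(n)
  t_nucl <- rep(Inf, length(segs))
  for (j in seq_along(segs)) {
    if (truth$k_nucl > 0 && truth$k_form > 0) {
      t_nucl[j] <- config$flush_time + stats::rexp(1, truth$k_nucl)
      cap_j <- segs[j] * max_monomers
      monomers <- monomers +
        pmin(cap_j, pmax(0, time - t_nucl[j]) * truth$k_form)
    }
  }
  if (any(monomers > max_monomers + 1e-9))
    stop("coverage mapping would exceed the tether length")
  alpha <- pmin(1, monomers / max_monomers)
  lp_t <- coverage_lp(alpha, truth$lp_bare,
                      if (truth$lp_full > truth$lp_bare) truth$lp_full
                      else truth$lp_bare * (1 + 1e-9))
  ext <- .wlc_invert(config$force, lp_t, truth$lc, 4.11)
  sd_f <- .noise_sd_at(config$noise_sd, config$force)
  if (sd_f > 0) ext <- ext + stats::rnorm(n, 0, sd_f)

  growth_end <- if (all(is.infinite(t_nucl))) NA_real_ else
    max(t_nucl[is.finite(t_nucl)] +
          segs[is.finite(t_nucl)] * max_monomers / truth$k_form)
  .new_trace(time, ext, config$force, 0, metadata = list(
    protocol = "assembly", seed = config$seed,
    sample_rate = config$sample_rate,
    flush_start = config$flush_time,
    t_nucl = if (all(is.infinite(t_nucl))) NA_real_ else
      min(t_nucl) - config$flush_time,
    t_nucl_segments = t_nucl,
    segment_fractions = segs,
    t_growth_end = growth_end,
    truth = unclass(truth)))
}

#' Simulate the ATP-driven compaction phase of a filament trace
#'
#' Extension decreases linearly at `k_comp` nm/s from `start_extension`;
#' rupture events arrive as a Poisson process at `truth$rupture_rate` and
#' each adds an abrupt upward jump (mean `truth$rupture_size_nm`) within one
#' sample, after which compaction resumes.  Once the compacted floor
#' (`floor_frac * lc`, default 10% of the contour length) is reached the
#' extension stays clamped there with the noise reduced by `floor_noise_factor`,
#' emulating the signature drop in bead-height fluctuation of the tight
#' compacted complex.
#'
#' @param config A [sim_config()] (constant force).
#' @param truth A [ground_truth()]; `k_comp` must be >= 0.
#' @param start_extension Extension in nm at the start of compaction; must
#'   exceed the compacted floor.
#' @param floor_frac Compacted floor as a fraction of the contour length.
#' @param floor_noise_factor Noise scale factor applied at the floor.
#'
#' @return An `fm_trace`; metadata records injected rupture times/sizes and
#'   the time the floor was reached.
#' @export
simulate_compaction_phase <- function(config, truth, start_extension,
                                      floor_frac = 0.1,
                                      floor_noise_factor = 0.2) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (truth$k_comp < 0) stop("k_comp must be >= 0")
  floor_ext <- floor_frac * truth$lc
  if (start_extension <= floor_ext)
    stop("start_extension must exceed the compacted floor")
  set.seed(config$seed)
  dt <- 1 / config$sample_rate
  time <- seq(0, config$duration, by = dt)
  n <- length(time)

  # event-driven construction of the noiseless path
  ext <- numeric(n)
  cur <- start_extension
  t_cur <- 0
  idx <- 1L
  rupture_times <- numeric(0)
  rupture_sizes <- numeric(0)
  t_floor <- NA_real_
  repeat {
    t_next_rupt <- if (truth$rupture_rate > 0)
      t_cur + stats::rexp(1, truth$rupture_rate) else Inf
    t_hit_floor <- if (truth$k_comp > 0)
      t_cur + (cur - floor_ext) / truth$k_comp else Inf
    t_stop <- min(t_next_rupt, t_hit_floor, config$duration)
    seg <- which(time[idx:n] <= t_stop) + idx - 1L
    if (length(seg)) {
      ext[seg] <- cur - truth$k_comp * (time[seg] - t_cur)
      idx <- seg[length(seg)] + 1L
    }
    if (t_stop >= config$duration || idx > n) break
    if (t_hit_floor <= t_next_rupt) {
      t_floor <- t_hit_floor
      ext[idx:n] <- floor_ext
      idx <- n + 1L
      break
    }
    jump <- max(0, stats::rnorm(1, truth$rupture_size_nm,
                                0.15 * truth$rupture_size_nm))
    cur <- cur - truth$k_comp * (t_next_rupt - t_cur) + jump
    rupture_times <- c(rupture_times, t_next_rupt)
    rupture_sizes <- c(rupture_sizes, jump)
    t_cur <- t_next_rupt
  }
  ext <- pmax(ext, floor_ext)

  sd_f <- .noise_sd_at(config$noise_sd, config$force)
  if (sd_f > 0) {
    sd_vec <- rep(sd_f, n)
    if (!is.na(t_floor)) sd_vec[time >= t_floor] <- sd_f * floor_noise_factor
    ext <- ext + stats::rnorm(n, 0, sd_vec)
  }
  .new_trace(time, ext, config$force, 0, metadata = list(
    protocol = "compaction", seed = config$seed,
    sample_rate = config$sample_rate, flush_start = config$flush_time,
    start_extension = start_extension, floor_extension = floor_ext,
    t_floor = t_floor, rupture_times = rupture_times,
    rupture_sizes = rupture_sizes, truth = unclass(truth)))
}

#' Simulate a force-ramp (dynamic force-extension) trace
#'
#' The applied force follows a log-linear profile between `f_range[1]` and
#' `f_range[2]` over the trace duration (emulating magnets approaching at
#' constant speed); the extension is the WLC response plus Gaussian noise.
#' In rupture mode (high-force ramps on compacted filaments) a rupture force
#' is drawn from Normal(`truth$rupture_force_mean`, `truth$rupture_force_sd`)
#' and the extension jumps from the compacted plateau to the bare-tether WLC
#' branch at that force.
#'
#' @param config A [sim_config()].
#' @param params A [wlc_params()] describing the tether mechanics.
#' @param noise_sd Gaussian extension noise sd in nm (constant over the ramp).
#' @param f_range Force range in pN, `c(min, max)`, both > 0.
#' @param rupture If `TRUE`, simulate a compacted filament that ruptures.
#' @param truth A [ground_truth()] (required in rupture mode).
#' @param floor_frac Compacted plateau as a fraction of the contour length
#'   (rupture mode).
#'
#' @return An `fm_trace`; in rupture mode the metadata records the drawn
#'   rupture force.
#' @export
simulate_force_ramp <- function(config, params, noise_sd = 0,
                                f_range = c(0.1, 8), rupture = FALSE,
                                truth = NULL, floor_frac = 0.1) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "wlc_params"))
  if (any(f_range <= 0)) stop("forces must be > 0")
  set.seed(config$seed)
  time <- seq(0, config$duration, by = 1 / config$sample_rate)
  n <- length(time)
  force <- f_range[1] * (f_range[2] / f_range[1])^(time / config$duration)
  f_rupt <- NA_real_
  if (rupture) {
    if (is.null(truth)) stop("rupture mode requires a ground_truth")
    f_rupt <- stats::rnorm(1, truth$rupture_force_mean,
                           truth$rupture_force_sd)
    ext <- ifelse(force < f_rupt, floor_frac * params$lc,
                  .wlc_invert(force, params$lp, params$lc, params$kbt))
  } else {
    ext <- .wlc_invert(force, params$lp, params$lc, params$kbt)
  }
  if (noise_sd > 0) ext <- ext + stats::rnorm(n, 0, noise_sd)
  .new_trace(time, ext, force, 0, metadata = list(
    protocol = "ramp", seed = config$seed, sample_rate = config$sample_rate,
    rupture_force = f_rupt,
    lp = params$lp, lc = params$lc, kbt = params$kbt))
}

#' Simulate a rotation-extension sweep
#'
#' Magnet turns sweep linearly over `turn_range` during the trace.  A
#' coilable tether loses `truth$pos_turn_slope` nm per added positive turn
#' and `truth$neg_turn_slope` nm per added negative turn from the zero-turn
#' apex; a non-coilable tether is insensitive to turns.
#'
#' @param config A [sim_config()]; `config$force` sets the apex extension
#'   through the filament WLC response.
#' @param truth A [ground_truth()].
#' @param coilable Logical; torsionally constrained tether or not.
#' @param turn_range Sweep range, `c(min_turns, max_turns)`.
#'
#' @return An `fm_trace` with a populated `turns` channel.
#' @export
simulate_rotation_extension <- function(config, truth, coilable = TRUE,
                                        turn_range = c(-50, 50)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed)
  time <- seq(0, config$duration, by = 1 / config$sample_rate)
  n <- length(time)
  turns <- turn_range[1] + (turn_range[2] - turn_range[1]) *
    time / config$duration
  apex <- .wlc_invert(config$force, truth$lp_full, truth$lc, 4.11)
  ext <- rep(apex, n)
  if (coilable) {
    ext <- apex - truth$pos_turn_slope * pmax(turns, 0) -
      truth$neg_turn_slope * pmax(-turns, 0)
  }
  sd_f <- .noise_sd_at(config$noise_sd, config$force)
  if (sd_f > 0) ext <- ext + stats::rnorm(n, 0, sd_f)
  ext <- pmax(ext, 0)
  .new_trace(time, ext, config$force, turns, metadata = list(
    protocol = "rotation", seed = config$seed,
    sample_rate = config$sample_rate, coilable = coilable,
    truth = unclass(truth)))
}

#' Simulate a binomial fractional-occupancy cohort
#'
#' For each concentration the true occupancy follows the Hill isotherm
#' \eqn{\alpha(c) = c^n / (K_D^n + c^n)}; the observed fraction is a
#' Binomial(`n_all`, alpha) draw divided by `n_all`, with the binomial
#' standard error \eqn{\sqrt{\alpha(1-\alpha)/N}} attached.
#'
#' @param concentrations Protein concentrations in nM, all > 0.
#' @param kd Apparent dissociation constant in nM, > 0.
#' @param n Hill coefficient, > 0.
#' @param n_all Number of tethers scored per concentration, >= 1.
#' @param seed Optional integer seed.
#'
#' @return A data frame with columns `concentration`, `alpha` (observed),
#'   `alpha_true`, `sigma_alpha`, `n_tethers`.
#' @export
simulate_occupancy_counts <- function(concentrations, kd, n, n_all,
                                      seed = NULL) {
  if (kd <= 0 || n <= 0) stop("kd and n must be > 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (n_all < 1) stop("n_all must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  a_true <- hill_alpha(concentrations, kd, n)
  k <- stats::rbinom(length(concentrations), n_all, a_true)
  f <- k / n_all
  data.frame(concentration = concentrations, alpha = f, alpha_true = a_true,
             sigma_alpha = sqrt(f * (1 - f) / n_all), n_tethers = n_all)
}

#' Simulate a labeled trace of a given outcome class
#'
#' Convenience generator for classifier validation: produces a constant-force
#' trace whose shape matches one of the four outcome classes (rise then
#' stable plateau; rise then compaction to the floor; compaction stopping
#' between the floor and below the bare extension; decay back to the bare
#' extension).
#'
#' @param config A [sim_config()].
#' @param truth A [ground_truth()].
#' @param class One of `"extended"`, `"fully_compacted"`,
#'   `"partially_compacted"`, `"dissociated"`.
#'
#' @return An `fm_trace` with metadata element `class_label`.
#' @export
simulate_classified_trace <- function(config, truth,
                                      class = c("extended", "fully_compacted",
                                                "partially_compacted",
                                                "dissociated")) {
  class <- match.arg(class)
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed)
  dt <- 1 / config$sample_rate
  time <- seq(0, config$duration, by = dt)
  n <- length(time)
  bare <- .wlc_invert(config$force, truth$lp_bare, truth$lc, 4.11)
  full <- .wlc_invert(config$force, truth$lp_full, truth$lc, 4.11)
  floor_ext <- 0.1 * truth$lc
  t_rise0 <- config$flush_time + 0.1 * (config$duration - config$flush_time)
  t_rise1 <- config$flush_time + 0.3 * (config$duration - config$flush_time)
  t_fall1 <- config$flush_time + 0.8 * (config$duration - config$flush_time)
  ramp01 <- function(t0, t1) pmin(1, pmax(0, (time - t0) / (t1 - t0)))
  target <- switch(class,
    extended = floor_ext,  # placeholder, overwritten below
    fully_compacted = floor_ext,
    partially_compacted = bare - 0.3 * (bare - floor_ext),
    dissociated = bare)
  ext <- bare + (full - bare) * ramp01(t_rise0, t_rise1)
  if (class != "extended")
    ext <- ext - (full - target) * ramp01(t_rise1 + 5, t_fall1)
  ext <- pmax(ext, floor_ext)
  sd_f <- .noise_sd_at(config$noise_sd, config$force)
  if (sd_f > 0) {
    sd_vec <- rep(sd_f, n)
    if (class == "fully_compacted") sd_vec[time >= t_fall1] <- 0.2 * sd_f
    ext <- ext + stats::rnorm(n, 0, sd_vec)
  }
  .new_trace(time, ext, config$force, 0, metadata = list(
    protocol = "assembly", seed = config$seed,
    sample_rate = config$sample_rate, flush_start = config$flush_time,
    class_label = class, bare_extension = bare, truth = unclass(truth)))
}
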
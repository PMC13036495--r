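# Segmentation and rate extraction from constant-force traces: low-pass
# filtering, nucleation detection, sliding-window formation and compaction
# slopes, rupture-event counting, four-way outcome classification and
# rotation-extension coilability.

#' Analysis window settings
#'
#' @param formation Sliding-window length in s for formation slopes
#'   (default 20).
#' @param compaction Sliding-window length in s for compaction slopes
#'   (default 50).
#' @param rupture Rise window in s for rupture counting (default 5).
#' @param lowpass Moving-average filter width in samples (default 58, i.e.
#'   1 s of raw signal at the standard acquisition rate).
#'
#' @return An `analysis_windows` object.
#' @export
analysis_windows <- function(formation = 20, compaction = 50, rupture = 5,
                             lowpass = 58) {
  if (any(c(formation, compaction, rupture) <= 0) || lowpass < 1)
    stop("all windows must be positive")
  structure(list(formation = formation, compaction = compaction,
                 rupture = rupture, lowpass = as.integer(lowpass)),
            class = "analysis_windows")
}

#' Centered moving-average filter
#'
#' Moving average over `window` samples, centered, with the window shrinking
#' symmetrically at the trace edges; the output stays aligned to the input
#' timestamps.
#'
#' @param trace An `fm_trace`.
#' @param window Filter width in samples (>= 1); `window = 1` is the
#'   identity.
#'
#' @return A filtered `fm_trace` with the same timestamps and metadata.
#' @export
lowpass <- function(trace, window = 58) {
  out <- trace
  out$extension <- .movavg(trace$extension, window)
  out
}

# centered moving average of a numeric vector, shrinking at the edges
.movavg <- function(x, window) {
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  h1 <- (as.integer(window) - 1L) %/% 2L
  h2 <- (as.integer(window) - 1L) - h1
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 1 Hz view of a trace: lowpass over `window` samples, decimated to one
# sample per second of acquisition.
.one_hz <- function(trace, window = 58) {
  sm <- lowpass(trace, window)
  step <- max(1L, as.integer(round(
    attr(trace, "metadata")$sample_rate %||% window)))
  idx <- seq(1L, nrow(sm), by = step)
  list(time = sm$time[idx], ext = sm$extension[idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the filament nucleation time in an assembly trace
#'
#' Automated surrogate for picking nucleation on 1 Hz low-pass filtered
#' traces: nucleation is the first instant after the protein flush where the
#' filtered extension exceeds the pre-flush baseline mean by `k_sd` baseline
#' standard deviations and stays above for at least `dwell` seconds (or to
#' the end of the trace, whichever is shorter).
#'
#' @param trace An `fm_trace` of an assembly experiment.
#' @param windows An [analysis_windows()].
#' @param flush_start Time in s when protein reaches the tether; taken from
#'   the trace metadata when `NULL`.
#' @param k_sd Threshold in baseline standard deviations (default 3).
#' @param dwell Minimum dwell above threshold in s (default 10).
#'
#' @return Waiting time in s from flush start to nucleation, or `NA` when no
#'   qualifying crossing exists ("no nucleation": the trace is excluded from
#'   rate estimates but still counted).
#' @export
detect_nucleation <- function(trace, windows = analysis_windows(),
                              flush_start = NULL, k_sd = 3, dwell = 10) {
  md <- trace_meta(trace)
  if (is.null(flush_start)) flush_start <- md$flush_start
  if (is.null(flush_start)) stop("flush_start not given and not in metadata")
  s <- .one_hz(trace, windows$lowpass)
  base <- s$ext[s$time < flush_start]
  if (length(base) < 3L) stop("baseline interval before the flush too short")
  thr <- mean(base) + k_sd * max(stats::sd(base), 1e-9)
  post <- which(s$time >= flush_start)
  above <- s$ext[post] > thr
  if (!any(above)) return(NA_real_)
  t_post <- s$time[post]
  t_end <- t_post[length(t_post)]
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    t0 <- t_post[starts[k]]
    t1 <- t_post[ends[k]]
    if (t1 - t0 >= min(dwell, t_end - t0)) return(t0 - flush_start)
  }
  NA_real_
}

# OLS slopes of the 1 Hz series in sliding windows of `width` s advanced one
# sample at a time; returns per-window slope and net signal change.
.window_slopes <- function(t, x, width) {
  n <- length(t)
  starts <- which(t <= t[n] - width)
  if (!length(starts) && n >= 2L) starts <- 1L
  slope <- net <- rep(NA_real_, length(starts))
  t0 <- t1 <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    sel <- s:max(which(t <= t[s] + width))
    if (length(sel) < 2L) next
    tt <- t[sel]; xx <- x[sel]
    slope[i] <- stats::cov(tt, xx) / stats::var(tt)
    net[i] <- xx[length(xx)] - xx[1L]
    t0[i] <- tt[1L]; t1[i] <- tt[length(tt)]
  }
  keep <- !is.na(slope)
  data.frame(t0 = t0[keep], t1 = t1[keep],
             slope = slope[keep], net = net[keep])
}

#' Filament formation rate from sliding-window slopes
#'
#' Local least-squares slopes of the 1 Hz filtered extension in sliding
#' windows (default 20 s) over the selected growth region; windows whose net
#' extension increase does not exceed twice the pre-flush baseline dispersion
#' are discarded, and the mean surviving slope is returned.
#'
#' @param trace An `fm_trace`.
#' @param region Time span `c(t0, t1)` in s of the growth phase.
#' @param windows An [analysis_windows()].
#' @param baseline_sd Standard deviation in nm of the raw signal before the
#'   protein flush; computed from the trace when `NULL`.
#' @param threshold_mode `"sd"` applies a threshold of `2 * baseline_sd` (nm,
#'   dimensionally consistent); `"variance"` applies the literal
#'   `2 * baseline_sd^2` (nm^2 compared against nm).
#'
#' @return Mean slope in nm/s of the surviving windows, or `NA` when no
#'   window survives ("below detection").
#' @export
formation_rate <- function(trace, region, windows = analysis_windows(),
                           baseline_sd = NULL,
                           threshold_mode = c("sd", "variance")) {
  threshold_mode <- match.arg(threshold_mode)
  if (is.null(baseline_sd)) baseline_sd <- .baseline_sd(trace)
  s <- .one_hz(trace, windows$lowpass)
  sel <- s$time >= region[1] & s$time <= region[2]
  if (sum(sel) < 2L) return(NA_real_)
  w <- .window_slopes(s$time[sel], s$ext[sel], windows$formation)
  thr <- if (threshold_mode == "sd") 2 * baseline_sd else 2 * baseline_sd^2
  keep <- w$net > thr
  if (!any(keep)) return(NA_real_)
  mean(w$slope[keep])
}

.baseline_sd <- function(trace) {
  md <- trace_meta(trace)
  fs <- md$flush_start
  if (is.null(fs)) stop("baseline_sd not given and no flush_start in metadata")
  base <- trace$extension[trace$time < fs]
  if (length(base) < 3L) stop("baseline interval before the flush too short")
  stats::sd(base)
}

#' Convert an extension growth rate to a monomer binding rate
#'
#' Normalizes a formation rate in nm/s by the extension gained per bound
#' monomer, `delta_l_300 * footprint_bp / tether_bp`, where `delta_l_300` is
#' the full-filament extension change of the tether at the working force.
#'
#' @param rate_nm_s Formation rate in nm/s.
#' @param delta_l_300 Extension change in nm upon complete filament
#'   formation; must be > 0.
#' @param footprint_bp Base pairs occluded per monomer (default 14).
#' @param tether_bp Tether length in bp (default 3149).
#'
#' @return Rate in monomers/s.
#' @examples
#' monomer_rate(2.8, delta_l_300 = 314.9)  # 2 monomers/s
#' @export
monomer_rate <- function(rate_nm_s, delta_l_300, footprint_bp = 14,
                         tether_bp = 3149) {
  if (delta_l_300 <= 0) stop("delta_l_300 must be > 0")
  rate_nm_s / (delta_l_300 * footprint_bp / tether_bp)
}

#' Filament compaction rate from sliding-window slopes
#'
#' Local least-squares slopes of the 1 Hz filtered extension in sliding
#' windows (default 50 s) over the selected compaction region.  Only
#' negative slopes are used, reported as positive magnitudes; magnitudes
#' below the 0.1 nm/s detection limit are excluded.  Windows overlapping a
#' supplied rupture time are discarded so that abrupt upward jumps do not
#' contaminate the slope estimate.
#'
#' @param trace An `fm_trace`.
#' @param region Time span `c(t0, t1)` in s of the compaction phase.
#' @param windows An [analysis_windows()].
#' @param ruptures Optional numeric vector of rupture times in s (e.g. the
#'   `time` column of [detect_ruptures()] output).
#' @param detection_limit Minimum window slope magnitude in nm/s
#'   (default 0.1).
#'
#' @return Mean compaction rate in nm/s (positive), or `NA` when every
#'   window is below detection.
#' @export
compaction_rate <- function(trace, region, windows = analysis_windows(),
                            ruptures = NULL, detection_limit = 0.1) {
  s <- .one_hz(trace, windows$lowpass)
  sel <- s$time >= region[1] & s$time <= region[2]
  if (sum(sel) < 2L) return(NA_real_)
  w <- .window_slopes(s$time[sel], s$ext[sel], windows$compaction)
  if (length(ruptures)) {
    clean <- vapply(seq_len(nrow(w)), function(i)
      !any(ruptures > w$t0[i] & ruptures < w$t1[i]), logical(1))
    w <- w[clean, , drop = FALSE]
  }
  mag <- -w$slope[w$slope < 0]
  mag <- mag[mag >= detection_limit]
  if (!length(mag)) return(NA_real_)
  mean(mag)
}

#' Detect rupture events during filament compaction
#'
#' Scans the 1 Hz averaged signal for upward excursions exceeding twice the
#' standard deviation of the raw signal before ATP addition within any
#' `windows$rupture`-second window; crossings closer than the rupture window
#' are merged into one event.
#'
#' @param trace An `fm_trace`.
#' @param baseline_sd Standard deviation in nm of the raw pre-ATP signal.
#' @param windows An [analysis_windows()].
#'
#' @return A data frame with columns `time` (s, position of the steepest
#'   rise within the event) and `size` (nm, largest rise within the event);
#'   zero rows when no event is found.
#' @export
detect_ruptures <- function(trace, baseline_sd,
                            windows = analysis_windows()) {
  if (baseline_sd <= 0) stop("baseline_sd must be > 0")
  s <- .one_hz(trace, windows$lowpass)
  n <- length(s$ext)
  lagmax <- max(1L, as.integer(round(windows$rupture)))
  thr <- 2 * baseline_sd
  rise <- rep(-Inf, n)
  for (k in seq_len(lagmax)) {
    idx <- seq_len(n - k)
    rise[idx] <- pmax(rise[idx], s$ext[idx + k] - s$ext[idx])
  }
  hit <- which(rise > thr)
  if (!length(hit)) return(data.frame(time = numeric(0), size = numeric(0)))
  gap <- c(Inf, diff(s$time[hit]))
  grp <- cumsum(gap >= windows$rupture)
  out <- lapply(split(hit, grp), function(ix) {
    lo <- min(ix)
    hi <- min(n, max(ix) + lagmax)
    d1 <- diff(s$ext[lo:hi])
    data.frame(time = s$time[lo + which.max(d1)],
               size = max(rise[ix]))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Classify the outcome of a constant-force filament trace
#'
#' Four-way classification of traces after nucleotide addition:
#' `fully_compacted` (ends at the compacted floor, and any supplied post-run
#' force-extension fit shows no compliant response), `partially_compacted`
#' (drops below the bare-tether extension without reaching a stable floor),
#' `dissociated` (extension decreased but never below the bare tether),
#' `extended` (extension only increased and remained stable).  Traces firing
#' none of the rules are labeled `unclassified` and counted — a deliberate
#' extension of the four-way scheme.
#'
#' @param trace An `fm_trace`.
#' @param bare_extension Bare-tether extension in nm at the working force,
#'   measured before the protein flush.
#' @param post_fit Optional `wlc_fit` of a force-extension run taken after
#'   the trace; a converged, accepted fit indicates a live mechanical
#'   response and vetoes `fully_compacted`.
#' @param windows An [analysis_windows()].
#' @param floor_level Extension in nm below which the tether counts as
#'   compacted to the floor; defaults to 25% of `bare_extension`.
#' @param tol Dead-band in nm around `bare_extension`; defaults to 6 times
#'   the filtered-trace baseline noise (never below 5 nm).
#'
#' @return A single character label.
#' @export
classify_trace <- function(trace, bare_extension, post_fit = NULL,
                           windows = analysis_windows(),
                           floor_level = NULL, tol = NULL) {
  s <- .one_hz(trace, windows$lowpass)
  if (is.null(floor_level)) floor_level <- 0.25 * bare_extension
  if (is.null(tol)) {
    md <- trace_meta(trace)
    fs <- md$flush_start %||% NA_real_
    base <- if (!is.na(fs)) s$ext[s$time < fs] else s$ext[seq_len(5L)]
    tol <- max(5, 6 * stats::sd(base))
    if (!is.finite(tol)) tol <- 5
  }
  n <- length(s$ext)
  tail_sel <- s$time >= s$time[n] - 10
  final <- mean(s$ext[tail_sel])
  peak <- max(s$ext)
  post_flat <- is.null(post_fit) || !isTRUE(post_fit$accepted)
  if (final <= floor_level && post_flat) return("fully_compacted")
  if (final < bare_extension - tol) return("partially_compacted")
  if (peak - final > tol && peak > bare_extension + tol) return("dissociated")
  if (peak > bare_extension + tol && final > bare_extension + tol)
    return("extended")
  "unclassified"
}

#' Propose formation/compaction analysis regions from phase boundaries
#'
#' Reproducible surrogate for manual region selection: the formation region
#' runs from the detected nucleation crossing to the first time the filtered
#' extension reaches 95% of its net rise above baseline; the compaction
#' region (when the trace decays) runs from the filtered maximum to the
#' first time the extension comes within noise of its final level.
#'
#' @param trace An `fm_trace`.
#' @param windows An [analysis_windows()].
#'
#' @return A list with elements `formation` and `compaction`, each `c(t0,
#'   t1)` in s or `NULL` when the phase is absent.
#' @export
propose_regions <- function(trace, windows = analysis_windows()) {
  md <- trace_meta(trace)
  s <- .one_hz(trace, windows$lowpass)
  fs <- md$flush_start %||% 0
  base <- mean(s$ext[s$time < fs])
  if (!is.finite(base)) base <- s$ext[1L]
  t_nucl <- tryCatch(detect_nucleation(trace, windows),
                     error = function(e) NA_real_)
  formation <- NULL
  i_peak <- which.max(s$ext)
  if (!is.na(t_nucl)) {
    t0 <- fs + t_nucl
    rise <- s$ext[i_peak] - base
    i_end <- which(s$time >= t0 & s$ext >= base + 0.95 * rise)[1L]
    if (!is.na(i_end) && s$time[i_end] > t0)
      formation <- c(t0, s$time[i_end])
  }
  compaction <- NULL
  n <- length(s$ext)
  final <- mean(s$ext[s$time >= s$time[n] - 10])
  if (s$ext[i_peak] - final > 0.2 * (s$ext[i_peak] - base) &&
      i_peak < n - 1L) {
    after <- i_peak:n
    i_done <- after[which(s$ext[after] <= final +
                            0.05 * (s$ext[i_peak] - final))[1L]]
    if (is.na(i_done)) i_done <- n
    compaction <- c(s$time[i_peak], s$time[i_done])
  }
  list(formation = formation, compaction = compaction)
}

#' Coilability of a tether from a rotation-extension sweep
#'
#' Fits separate lines to the positive-turn and negative-turn branches of a
#' rotation-extension trace.  The tether is coilable when the magnitude of
#' the positive-branch slope exceeds `se_factor` times its standard error
#' (a coilable tether loses extension when positive turns are added).
#'
#' @param trace An `fm_trace` from a rotation sweep (populated `turns`).
#' @param se_factor Detection threshold in slope standard errors (default 3).
#'
#' @return A list with `coilable` (logical), `pos_slope` and `neg_slope`
#'   (extension drop in nm per added positive / negative turn) and their
#'   standard errors.
#' @export
coilability_check <- function(trace, se_factor = 3) {
  pos <- trace$turns > 0.5
  neg <- trace$turns < -0.5
  if (sum(pos) < 3L || sum(neg) < 3L)
    stop("rotation sweep must cover both turn directions")
  fit_branch <- function(sel, sign) {
    fit <- stats::lm(extension ~ turns, data = trace[sel, ])
    co <- summary(fit)$coefficients
    # drop per added turn in that direction (positive value = extension loss)
    c(slope = -sign * co["turns", "Estimate"], se = co["turns", "Std. Error"])
  }
  p <- fit_branch(pos, +1)
  ng <- fit_branch(neg, -1)
  list(coilable = abs(p[["slope"]]) > se_factor * p[["se"]],
       pos_slope = p[["slope"]], pos_se = p[["se"]],
       neg_slope = ng[["slope"]], neg_se = ng[["se"]])
}
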
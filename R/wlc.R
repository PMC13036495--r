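# Inextensible worm-like chain mechanics: force law, its analytic integral
# (the "energy" transform used for fitting noisy force-extension data),
# numerical inversion, and the fitting procedure with its acceptance bounds.

#' Worm-like chain parameter set
#'
#' Bundle the persistence length, contour length and thermal energy that
#' parameterize the inextensible worm-like chain (WLC) model.
#'
#' @param lp Persistence length in nm (bending stiffness length scale).
#'   May be a vector (e.g. a coverage-dependent stiffness along a trace).
#' @param lc Contour length in nm (fully stretched tether length).
#' @param kbt Thermal energy \eqn{k_B T} in pN nm. Default 4.11 (25 C).
#'
#' @return An object of class `wlc_params`.
#' @examples
#' p <- wlc_params(lp = 45, lc = 896)
#' wlc_force(0.5 * 896, p)
#' @export
wlc_params <- function(lp, lc, kbt = 4.11) {
  if (any(!is.finite(lp)) || any(lp <= 0)) stop("lp must be finite and > 0")
  if (!is.numeric(lc) || length(lc) != 1L || !is.finite(lc) || lc <= 0)
    stop("lc must be a single finite value > 0")
  if (!is.numeric(kbt) || length(kbt) != 1L || kbt <= 0)
    stop("kbt must be a single value > 0")
  structure(list(lp = lp, lc = lc, kbt = kbt), class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("WLC parameters: Lp = %s nm, Lc = %.6g nm, kBT = %.4g pN nm\n",
              paste(signif(x$lp, 6), collapse = "/"), x$lc, x$kbt))
  invisible(x)
}

#' WLC restoring force at a given extension
#'
#' The inextensible worm-like chain interpolation formula
#' \deqn{F(L) = \frac{k_B T}{L_p}\left[\frac{1}{4(1 - L/L_c)^2} -
#'   \frac{1}{4} + \frac{L}{L_c}\right],}
#' strictly increasing in extension and diverging as the extension approaches
#' the contour length.
#'
#' @param extension Tether end-to-end extension in nm; must satisfy
#'   `0 <= extension < lc`. Vectorized.
#' @param params A [wlc_params()] object.
#'
#' @return Force in pN, same length as `extension` (recycled against `lp`).
#' @export
wlc_force <- function(extension, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(!is.finite(extension)) || any(extension < 0))
    stop("extension must be finite and >= 0")
  if (any(extension >= params$lc))
    stop("extension must be smaller than the contour length lc")
  x <- extension / params$lc
  (params$kbt / params$lp) * (0.25 / (1 - x)^2 - 0.25 + x)
}

#' Stretching energy of the WLC at a given extension
#'
#' Closed-form integral of [wlc_force()] from zero extension:
#' \deqn{E(L) = \int_0^{L} F\,dL' = \frac{1}{4}\,
#'   \frac{k_B T\, L^2 (2L - 3L_c)}{L_p L_c (L - L_c)}.}
#' Fitting this accumulated quantity instead of the raw force-extension
#' samples suppresses the Brownian fluctuations of the bead position.
#'
#' @inheritParams wlc_force
#' @return Energy in pN nm.
#' @export
wlc_energy <- function(extension, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(!is.finite(extension)) || any(extension < 0))
    stop("extension must be finite and >= 0")
  if (any(extension >= params$lc))
    stop("extension must be smaller than the contour length lc")
  L <- extension
  lc <- params$lc
  0.25 * params$kbt * L^2 * (2 * L - 3 * lc) / (params$lp * lc * (L - lc))
}

# Vectorized bracketed bisection for the extension solving F(L) = force.
# lp may be a vector (coverage-dependent stiffness); 80 bisection steps give
# |dF|/F far below 1e-9 everywhere on (0, lc).
.wlc_invert <- function(force, lp, lc, kbt) {
  n <- max(length(force), length(lp))
  force <- rep_len(force, n)
  lp <- rep_len(lp, n)
  target <- force * lp / kbt
  lo <- rep.int(0, n)
  hi <- rep.int(1 - 1e-12, n)
  for (i in seq_len(80L)) {
    mid <- 0.5 * (lo + hi)
    below <- (0.25 / (1 - mid)^2 - 0.25 + mid) < target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  0.5 * (lo + hi) * lc
}

#' Extension of a WLC at a given force
#'
#' Numerically inverts [wlc_force()] by bracketed bisection on
#' \eqn{(0, L_c)}; the solution exists and is unique for any positive force.
#'
#' @param force Applied force in pN, > 0. Vectorized.
#' @param params A [wlc_params()] object (`lp` may be a vector and is
#'   recycled against `force`).
#'
#' @return Extension in nm.
#' @examples
#' invert_wlc(0.1, wlc_params(45, 896))  # ~47% of the contour length
#' @export
invert_wlc <- function(force, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(!is.finite(force)) || any(force <= 0))
    stop("force must be finite and > 0")
  .wlc_invert(force, params$lp, params$lc, params$kbt)
}

#' Map fractional filament occupancy to an effective persistence length
#'
#' The square root of the inverse persistence length is interpolated linearly
#' between the bare-tether and full-filament values, so that the simulator and
#' the occupancy estimator ([fractional_occupancy()]) are exact inverses of
#' one another.
#'
#' @param alpha Fractional occupancy in \[0, 1\]. Vectorized.
#' @param lp_bare Persistence length of the bare tether in nm.
#' @param lp_full Persistence length of the complete filament in nm;
#'   must exceed `lp_bare`.
#'
#' @return Effective persistence length in nm.
#' @export
coverage_lp <- function(alpha, lp_bare, lp_full) {
  if (lp_bare <= 0 || lp_full <= 0 || lp_full <= lp_bare)
    stop("need 0 < lp_bare < lp_full")
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0, 1]")
  s <- sqrt(1 / lp_bare) + alpha * (sqrt(1 / lp_full) - sqrt(1 / lp_bare))
  1 / s^2
}

# cumulative trapezoid of y over x (same length, x sorted), starting at 0
.cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
}

#' Fit the WLC model to a force-extension curve in the energy domain
#'
#' Implements the integrated-energy fitting procedure: samples are sorted by
#' extension (duplicate extensions averaged), the measured stretching energy
#' is accumulated by the trapezoid rule, and the closed-form energy curve
#' ([wlc_energy()], plus a free additive offset absorbing the unobserved
#' integral below the smallest sampled extension) is fitted by
#' Levenberg-Marquardt least squares with free persistence and contour
#' lengths.  Results are flagged against the acceptance window
#' \eqn{0 \le L_p \le 500} nm and \eqn{700 \le L_c \le 2000} nm;
#' out-of-window fits are retained, never dropped.
#'
#' A list of replicate curves is fitted individually and the mean and standard
#' deviation of the accepted parameters are reported alongside the per-curve
#' results.
#'
#' @param curve A data frame with columns `extension` (nm) and `force` (pN)
#'   in acquisition (time) order, at least 50 points spanning a >= 5-fold
#'   force range, or a list of such data frames (replicates).
#' @param kbt Thermal energy in pN nm.
#' @param bounds Length-4 numeric acceptance window
#'   `c(lp_min, lp_max, lc_min, lc_max)` in nm.
#' @param smooth_window Moving-average width in samples applied to both
#'   channels in acquisition order before integrating (default 58, the
#'   standard 1-second average of the raw signal; set to 1 to disable).
#'   Averaging the bead position over the slow magnet motion suppresses the
#'   Brownian noise of the extension coordinate, which would otherwise bias
#'   the accumulated-energy curve near the contour length.
#'
#' @return For a single curve, a `wlc_fit` object with elements `params`
#'   ([wlc_params()]), `accepted`, `residual_norm`, `converged`.  For a list
#'   of curves, a `wlc_fit_cohort` with `fits` (per-curve results), `lp_mean`,
#'   `lp_sd`, `lc_mean`, `lc_sd` over accepted fits and `n_accepted`.
#' @export
fit_wlc_integrated <- function(curve, kbt = 4.11,
                               bounds = c(0, 500, 700, 2000),
                               smooth_window = 58) {
  if (is.data.frame(curve))
    return(.fit_wlc_one(curve, kbt, bounds, smooth_window))
  fits <- lapply(curve, .fit_wlc_one, kbt = kbt, bounds = bounds,
                 smooth_window = smooth_window)
  ok <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  lp <- vapply(fits[ok], function(f) f$params$lp, numeric(1))
  lc <- vapply(fits[ok], function(f) f$params$lc, numeric(1))
  structure(list(fits = fits, n_accepted = sum(ok),
                 lp_mean = mean(lp), lp_sd = stats::sd(lp),
                 lc_mean = mean(lc), lc_sd = stats::sd(lc)),
            class = "wlc_fit_cohort")
}

.check_curve <- function(curve) {
  if (!all(c("extension", "force") %in% names(curve)))
    stop("curve needs columns 'extension' and 'force'")
  if (any(curve$force <= 0)) stop("forces must be > 0")
  if (nrow(curve) < 50L)
    stop("need at least 50 force-extension points")
  if (max(curve$force) / min(curve$force) < 5)
    stop("curve must span at least a 5-fold force range")
  invisible(curve)
}

.fit_wlc_one <- function(curve, kbt, bounds, smooth_window = 58) {
  .check_curve(curve)
  ext <- .movavg(curve$extension, smooth_window)
  frc <- .movavg(curve$force, smooth_window)
  ord <- order(ext)
  e <- ext[ord]
  f <- frc[ord]
  if (anyDuplicated(e)) {
    f <- as.numeric(tapply(f, e, mean))
    e <- sort(unique(e))
  }
  E <- .cumtrapz(e, f)
  lc0 <- 1.05 * max(e)
  # the measured integral starts at the smallest sampled extension, so the
  # model is the analytic energy referenced to that point (no free offset,
  # which would make very large lc degenerate)
  energy <- function(L, lp, lc)
    0.25 * kbt * L^2 * (2 * L - 3 * lc) / (lp * lc * (L - lc))
  e0 <- e[1L]
  model <- function(lp, lc) energy(e, lp, lc) - energy(e0, lp, lc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      E ~ model(lp, lc),
      start = list(lp = 50, lc = lc0),
      lower = c(lp = 1e-3, lc = max(e) * (1 + 1e-6)),
      upper = c(lp = 1e4, lc = 20 * max(e)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, accepted = FALSE, converged = FALSE,
                          residual_norm = NA_real_),
                     class = "wlc_fit"))
  }
  cf <- stats::coef(fit)
  accepted <- cf[["lp"]] >= bounds[1] && cf[["lp"]] <= bounds[2] &&
    cf[["lc"]] >= bounds[3] && cf[["lc"]] <= bounds[4]
  structure(list(params = wlc_params(cf[["lp"]], cf[["lc"]], kbt),
                 accepted = accepted, converged = TRUE,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("WLC fit: did not converge\n")
  } else {
    cat(sprintf("WLC fit: Lp = %.4g nm, Lc = %.5g nm (%s)\n",
                x$params$lp, x$params$lc,
                if (x$accepted) "accepted" else "outside acceptance window"))
  }
  invisible(x)
}

#' @export
print.wlc_fit_cohort <- function(x, ...) {
  cat(sprintf(
    "WLC cohort fit: %d/%d accepted; Lp = %.4g +/- %.3g nm, Lc = %.5g +/- %.3g nm\n",
    x$n_accepted, length(x$fits), x$lp_mean, x$lp_sd, x$lc_mean, x$lc_sd))
  invisible(x)
}

#' Fit the WLC force law directly to a force-extension curve
#'
#' Plain weighted-free least squares of [wlc_force()] against the raw samples,
#' provided as the baseline the integrated-energy procedure is compared
#' against (the energy-domain fit is less sensitive to Brownian position
#' noise).
#'
#' @inheritParams fit_wlc_integrated
#' @return A `wlc_fit` object.
#' @export
fit_wlc_direct <- function(curve, kbt = 4.11, bounds = c(0, 500, 700, 2000)) {
  .check_curve(curve)
  e <- curve$extension
  f <- curve$force
  model <- function(lp, lc) {
    x <- e / lc
    (kbt / lp) * (0.25 / (1 - x)^2 - 0.25 + x)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ model(lp, lc),
      start = list(lp = 50, lc = 1.05 * max(e)),
      lower = c(lp = 1e-3, lc = max(e) * (1 + 1e-6)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) NULL)
  if (is.null(fit)) {
    return(structure(list(params = NULL, accepted = FALSE, converged = FALSE,
                          residual_norm = NA_real_),
                     class = "wlc_fit"))
  }
  cf <- stats::coef(fit)
  accepted <- cf[["lp"]] >= bounds[1] && cf[["lp"]] <= bounds[2] &&
    cf[["lc"]] >= bounds[3] && cf[["lc"]] <= bounds[4]
  structure(list(params = wlc_params(cf[["lp"]], cf[["lc"]], kbt),
                 accepted = accepted, converged = TRUE,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "wlc_fit")
}

#' Locate the rupture force on a high-force loading curve
#'
#' Automated surrogate for manual rupture picking on force ramps of compacted
#' filaments: finds the largest single-sample extension increase; if it
#' exceeds `jump_threshold` the applied force at that sample is reported.
#'
#' @param curve Data frame with columns `extension` (nm) and `force` (pN),
#'   ordered in time (loading direction).
#' @param jump_threshold Minimum single-sample extension jump in nm counted
#'   as a rupture (default 50).
#'
#' @return Numeric vector of rupture forces in pN; empty when no jump exceeds
#'   the threshold (a valid outcome, not an error).
#' @export
extract_rupture_forces <- function(curve, jump_threshold = 50) {
  if (!all(c("extension", "force") %in% names(curve)))
    stop("curve needs columns 'extension' and 'force'")
  d <- diff(curve$extension)
  if (length(d) == 0L || max(d) <= jump_threshold) return(numeric(0))
  curve$force[which.max(d) + 1L]
}
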
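# Occupancy inference: persistence-length normalization to fractional
# occupancy, binomial fraction errors, and the weighted Hill fit with case
# bootstrap.

#' Hill binding isotherm
#'
#' \eqn{\alpha(c) = c^n / (K_D^n + c^n)}; equals 1/2 exactly at
#' \eqn{c = K_D} for every Hill coefficient.
#'
#' @param conc Concentration (nM). Vectorized.
#' @param kd Apparent dissociation constant (nM), > 0.
#' @param n Hill coefficient, > 0.
#' @return Fractional occupancy.
#' @export
hill_alpha <- function(conc, kd, n) {
  if (kd <= 0 || n <= 0) stop("kd and n must be > 0")
  1 / (1 + (kd / conc)^n)
}

#' Fractional occupancy from a persistence length
#'
#' Normalizes a measured persistence length to the fractional filament
#' occupancy
#' \deqn{\alpha = \frac{\sqrt{1/L_{p,i}} - \sqrt{1/\bar L_p}}
#'   {\sqrt{1/L_{p,\mathrm{full}}} - \sqrt{1/\bar L_p}},}
#' where \eqn{\bar L_p} is the mean bare-tether persistence length (the
#' \eqn{\alpha = 0} anchor) and \eqn{L_{p,\mathrm{full}}} the persistence
#' length of the complete filament (the saturating-concentration anchor).
#' Noisy inputs may fall outside \[0, 1\]; values are returned unclamped
#' with a warning attribute `outside_unit` so the fit is not biased near the
#' boundaries.
#'
#' @param lp_i Measured persistence length(s) in nm, > 0. Vectorized.
#' @param lp_bare_mean Mean bare-tether persistence length in nm, > 0.
#' @param lp_300 Complete-filament persistence length in nm; must differ
#'   from `lp_bare_mean`.
#'
#' @return Fractional occupancy, unclamped, with logical attribute
#'   `outside_unit` flagging elements outside \[0, 1\].
#' @export
fractional_occupancy <- function(lp_i, lp_bare_mean, lp_300) {
  if (any(lp_i <= 0) || lp_bare_mean <= 0 || lp_300 <= 0)
    stop("persistence lengths must be > 0")
  den <- sqrt(1 / lp_300) - sqrt(1 / lp_bare_mean)
  if (den == 0) stop("degenerate normalization: lp_300 equals lp_bare_mean")
  a <- (sqrt(1 / lp_i) - sqrt(1 / lp_bare_mean)) / den
  structure(a, outside_unit = a < 0 | a > 1)
}

#' Relative event fraction with binomial standard error
#'
#' @param n_i Number of events of the class of interest, `0 <= n_i <= n_all`.
#' @param n_all Total number of events, >= 1.
#'
#' @return A list of class `fraction_error` with `f_rel`, `delta_f`
#'   (\eqn{\sqrt{f(1-f)/N}}), `n_i`, `n_all`.
#' @examples
#' binomial_error(50, 100)  # f = 0.5, delta_f = 0.05
#' @export
binomial_error <- function(n_i, n_all) {
  if (n_all < 1) stop("n_all must be >= 1")
  if (n_i < 0 || n_i > n_all) stop("need 0 <= n_i <= n_all")
  f <- n_i / n_all
  structure(list(f_rel = f, delta_f = sqrt(f * (1 - f) / n_all),
                 n_i = n_i, n_all = n_all),
            class = "fraction_error")
}

# Weighted Hill fit in log-parameter space (kd = exp(lk), n = exp(ln)):
# smooth near-degenerate resamples (e.g. all points saturated) instead of a
# singular Jacobian at a hard kd bound.  Multi-start for robustness; the
# result is clamped to the search box.
.hill_nls <- function(conc, alpha, w, kd0, n0, kd_max) {
  starts <- list(c(log(kd0), log(n0)),
                 c(log(min(conc)), log(2)),
                 c(log(max(conc)), log(0.5)))
  best <- NULL
  best_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        alpha ~ 1 / (1 + exp(exp(ln) * (lk - log(conc)))),
        start = list(lk = s[1], ln = s[2]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(err) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::resid(fit)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- stats::coef(fit)
    }
  }
  if (is.null(best)) stop("Hill fit did not converge from any start")
  c(kd = min(max(exp(best[["lk"]]), 1e-9), kd_max),
    n = min(max(exp(best[["ln"]]), 1e-3), 10))
}

#' Weighted Hill fit with case-resampling bootstrap
#'
#' Fits the Hill isotherm to occupancy points by nonlinear least squares
#' weighted by the inverse squared uncertainties, then case-resamples the
#' points with replacement `n_boot` times and refits.  The reported point
#' estimates are the means of the bootstrap estimates, with their standard
#' deviations as uncertainties; all bootstrap draws are retained.
#'
#' @param points Data frame with columns `concentration` (nM), `alpha`, and
#'   `sigma_alpha` (e.g. from [simulate_occupancy_counts()] or
#'   [fractional_occupancy()] plus [binomial_error()]).  At least three
#'   distinct concentrations are required for an identifiable fit.
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param sigma_floor Floor applied to zero or tiny uncertainties before
#'   weighting.  The default (`NULL`) uses half the smallest positive
#'   uncertainty among the points: a binomial standard error of exactly zero
#'   at an observed fraction of 0 or 1 understates the real uncertainty, and
#'   an uncapped weight would pin the fit to the saturated points.
#' @param resample `"case"` (resample points with replacement) or `"none"`
#'   (refit the original points every time; with `n_boot = 1` this
#'   reproduces the plain weighted fit).
#' @param max_fail Maximum tolerated fraction of non-converged bootstrap
#'   refits before the fit errors out (default 0.2).
#'
#' @return A `hill_fit` object: `kd`, `n_hill` (bootstrap-mean point
#'   estimates), `kd_sd`, `n_sd`, `kd_plain`, `n_plain` (the single weighted
#'   fit), `boot` (data frame of draws), `n_boot`, `n_failed`, `degenerate`.
#' @export
hill_fit <- function(points, n_boot = 1000, sigma_floor = NULL,
                     resample = c("case", "none"), max_fail = 0.2) {
  resample <- match.arg(resample)
  need <- c("concentration", "alpha", "sigma_alpha")
  if (!all(need %in% names(points)))
    stop("points needs columns concentration, alpha, sigma_alpha")
  if (any(points$concentration <= 0)) stop("concentrations must be > 0")
  if (n_boot < 1) stop("n_boot must be >= 1")
  conc <- points$concentration
  if (length(unique(conc)) < 3L) {
    return(structure(list(kd = NA_real_, n_hill = NA_real_,
                          kd_sd = NA_real_, n_sd = NA_real_,
                          degenerate = TRUE, n_boot = 0L, n_failed = 0L,
                          boot = NULL),
                     class = "hill_fit"))
  }
  if (is.null(sigma_floor)) {
    pos <- points$sigma_alpha[points$sigma_alpha > 0]
    sigma_floor <- if (length(pos)) min(pos) / 2 else 1e-3
  }
  w <- 1 / pmax(points$sigma_alpha, sigma_floor)^2
  kd0 <- exp(mean(log(unique(conc))))
  kd_max <- 10 * max(conc)
  plain <- tryCatch(.hill_nls(conc, points$alpha, w, kd0, 1, kd_max),
                    error = function(e) c(kd = NA_real_, n = NA_real_))
  m <- nrow(points)
  draws <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("kd", "n")))
  for (b in seq_len(n_boot)) {
    idx <- if (resample == "case") sample.int(m, m, replace = TRUE)
           else seq_len(m)
    if (length(unique(conc[idx])) < 3L) next
    draws[b, ] <- tryCatch(
      .hill_nls(conc[idx], points$alpha[idx], w[idx], kd0, 1, kd_max),
      error = function(e) c(NA_real_, NA_real_))
  }
  failed <- sum(is.na(draws[, 1]))
  if (failed > max_fail * n_boot)
    stop(sprintf("Hill fit failed: %d of %d bootstrap refits did not converge",
                 failed, n_boot))
  ok <- stats::complete.cases(draws)
  structure(list(kd = mean(draws[ok, "kd"]),
                 n_hill = mean(draws[ok, "n"]),
                 kd_sd = stats::sd(draws[ok, "kd"]),
                 n_sd = stats::sd(draws[ok, "n"]),
                 kd_plain = plain[["kd"]], n_plain = plain[["n"]],
                 boot = as.data.frame(draws[ok, , drop = FALSE]),
                 n_boot = as.integer(n_boot), n_failed = as.integer(failed),
                 degenerate = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Hill fit: degenerate input (fewer than 3 distinct concentrations)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Hill fit (%d bootstrap samples): KD = %.3g +/- %.2g nM, n = %.3g +/- %.2g\n",
    x$n_boot, x$kd, x$kd_sd, x$n_hill, x$n_sd))
  invisible(x)
}
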
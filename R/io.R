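# Trace file format (TSV with '#'-prefixed metadata header), run
# configuration, and the batch pipeline that dispatches traces by protocol
# and aggregates a cohort report.

.flatten_meta <- function(md) {
  out <- list()
  for (k in names(md)) {
    v <- md[[k]]
    if (is.list(v)) {
      for (k2 in names(v)) if (!is.null(v[[k2]]) && length(v[[k2]]) >= 1L)
        out[[paste0(k, ".", k2)]] <- v[[k2]]
    } else if (!is.null(v) && length(v) >= 1L) {
      out[[k]] <- v
    }
  }
  out
}

.unflatten_meta <- function(flat) {
  md <- list()
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      if (is.null(md[[parts[1]]])) md[[parts[1]]] <- list()
      md[[parts[1]]][[parts[2]]] <- flat[[k]]
    } else {
      md[[k]] <- flat[[k]]
    }
  }
  md
}

#' Write a trace to a tab-separated file
#'
#' One trace per file: `#`-prefixed `key = value` metadata header lines
#' followed by a header row and the columns `time_s`, `extension_nm`,
#' `force_pN`, `turns`.  Numeric metadata is written with full precision so
#' a write/read round trip is lossless.
#'
#' @param trace An `fm_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  md <- .flatten_meta(trace_meta(trace) %||% list())
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(md)) {
    v <- md[[k]]
    v <- if (is.numeric(v)) paste(format(v, digits = 17), collapse = ",")
         else paste(as.character(v), collapse = ",")
    writeLines(sprintf("# %s = %s", k, v), con)
  }
  writeLines("time_s\textension_nm\tforce_pN\tturns", con)
  utils::write.table(
    data.frame(format(trace$time, digits = 17),
               format(trace$extension, digits = 17),
               format(trace$force, digits = 17),
               format(trace$turns, digits = 17)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path Path to a trace TSV file.
#' @return An `fm_trace` with its metadata restored.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  flat <- list()
  for (i in seq_len(n_meta)) {
    m <- regmatches(lines[i],
                    regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      stop(sprintf("%s:%d: malformed metadata header line", path, i))
    vals <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    flat[[m[2]]] <- if (length(vals) && !anyNA(num)) num else vals
  }
  header <- strsplit(lines[n_meta + 1L], "\t", fixed = TRUE)[[1]]
  need <- c("time_s", "extension_nm", "force_pN", "turns")
  missing_cols <- setdiff(need, header)
  if (length(missing_cols))
    stop(sprintf("%s:%d: missing required column(s): %s", path, n_meta + 1L,
                 paste(missing_cols, collapse = ", ")))
  df <- utils::read.table(text = lines[-seq_len(n_meta + 1L)], sep = "\t",
                          col.names = header)
  if (any(diff(df$time_s) <= 0)) stop(sprintf("%s: non-monotone time", path))
  .new_trace(df$time_s, df$extension_nm, df$force_pN, df$turns,
             metadata = .unflatten_meta(flat))
}

#' Pipeline run configuration
#'
#' All thresholds and defaults of the analysis stages in one validated
#' record; unknown settings are rejected by R's argument matching.  The
#' record carries a provenance stamp (package version plus the serialized
#' settings) that [run_pipeline()] copies into every report.
#'
#' @param kbt Thermal energy in pN nm.
#' @param windows An [analysis_windows()].
#' @param wlc_bounds Acceptance window for WLC fits,
#'   `c(lp_min, lp_max, lc_min, lc_max)` in nm.
#' @param nucleation_k_sd,nucleation_dwell Nucleation threshold (baseline
#'   sds) and dwell (s).
#' @param formation_threshold `"sd"` or `"variance"` (see
#'   [formation_rate()]).
#' @param detection_limit Compaction detection limit in nm/s.
#' @param jump_threshold Rupture-force jump threshold in nm.
#' @param n_boot Bootstrap samples for Hill fits.
#' @param seed Root seed; per-trace seeds are derived from it.
#'
#' @return A `run_config` object.
#' @export
run_config <- function(kbt = 4.11, windows = analysis_windows(),
                       wlc_bounds = c(0, 500, 700, 2000),
                       nucleation_k_sd = 3, nucleation_dwell = 10,
                       formation_threshold = "sd", detection_limit = 0.1,
                       jump_threshold = 50, n_boot = 1000, seed = 1L) {
  cfg <- list(kbt = kbt, windows = windows, wlc_bounds = wlc_bounds,
              nucleation_k_sd = nucleation_k_sd,
              nucleation_dwell = nucleation_dwell,
              formation_threshold = formation_threshold,
              detection_limit = detection_limit,
              jump_threshold = jump_threshold,
              n_boot = n_boot, seed = as.integer(seed))
  plain <- cfg
  plain$windows <- unclass(plain$windows)
  cfg$stamp <- list(
    package = as.character(utils::packageVersion("filamech")),
    settings = as.character(jsonlite::toJSON(plain, auto_unbox = TRUE,
                                             digits = NA)))
  structure(cfg, class = "run_config")
}

.analyze_one <- function(path, protocol, config) {
  trace <- read_trace(path)
  w <- config$windows
  if (protocol == "assembly") {
    t_nucl <- detect_nucleation(trace, w, k_sd = config$nucleation_k_sd,
                                dwell = config$nucleation_dwell)
    regions <- propose_regions(trace, w)
    form <- if (!is.null(regions$formation))
      formation_rate(trace, regions$formation, w,
                     threshold_mode = config$formation_threshold)
      else NA_real_
    md <- trace_meta(trace)
    bare <- if (!is.null(md$bare_extension)) md$bare_extension
            else mean(trace$extension[trace$time < md$flush_start])
    list(protocol = protocol, t_nucl = t_nucl, formation_rate_nm = form,
         class_label = classify_trace(trace, bare, windows = w))
  } else if (protocol == "compaction") {
    regions <- propose_regions(trace, w)
    base_sd <- tryCatch(.baseline_sd(trace), error = function(e) NULL)
    rupt <- if (!is.null(base_sd)) detect_ruptures(trace, base_sd, w)
            else data.frame(time = numeric(0), size = numeric(0))
    comp <- if (!is.null(regions$compaction))
      compaction_rate(trace, regions$compaction, w, ruptures = rupt$time,
                      detection_limit = config$detection_limit)
      else NA_real_
    list(protocol = protocol, compaction_rate = comp, ruptures = rupt)
  } else if (protocol == "ramp") {
    fit <- fit_wlc_integrated(
      data.frame(extension = trace$extension, force = trace$force),
      kbt = config$kbt, bounds = config$wlc_bounds)
    list(protocol = protocol, fit = fit)
  } else if (protocol == "rotation") {
    list(protocol = protocol, coilability = coilability_check(trace))
  } else {
    stop(sprintf("unknown protocol '%s'", protocol))
  }
}

#' Run the analysis pipeline over a cohort manifest
#'
#' Dispatches every trace listed in the manifest to the stage sequence
#' matching its protocol (assembly traces to nucleation/formation/
#' classification, compaction traces to rupture detection and compaction
#' rates, force ramps to the integrated WLC fit, rotation sweeps to the
#' coilability check) and aggregates cohort summaries.  Per-trace failures
#' are caught and reported without aborting the cohort, and aggregates are
#' invariant to the manifest row order.
#'
#' @param manifest Data frame with columns `path` and `protocol` (one of
#'   `"assembly"`, `"compaction"`, `"ramp"`, `"rotation"`).
#' @param config A [run_config()].
#'
#' @return An `fm_report`: `per_trace` (named by path), `errors`, and
#'   `aggregates` (rate means/sds, class counts and fractions with binomial
#'   errors, pooled WLC parameters), plus the provenance `stamp`.
#' @export
run_pipeline <- function(manifest, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (nrow(manifest) == 0L) {
    return(structure(list(per_trace = list(), errors = list(),
                          aggregates = list(n_traces = 0L),
                          stamp = config$stamp),
                     class = "fm_report"))
  }
  if (!all(c("path", "protocol") %in% names(manifest)))
    stop("manifest needs columns 'path' and 'protocol'")
  per <- list()
  errs <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    res <- tryCatch(.analyze_one(p, manifest$protocol[i], config),
                    error = function(e) e)
    if (inherits(res, "error")) errs[[p]] <- conditionMessage(res)
    else per[[p]] <- res
  }
  agg <- list(n_traces = nrow(manifest), n_failed = length(errs))
  grab <- function(field, proto) {
    v <- vapply(per, function(r)
      if (r$protocol == proto && !is.null(r[[field]]))
        as.numeric(r[[field]][1]) else NA_real_, numeric(1))
    v[!is.na(v)]
  }
  tn <- grab("t_nucl", "assembly")
  if (length(tn)) agg$k_nucl <- 1 / mean(tn)
  fr <- grab("formation_rate_nm", "assembly")
  if (length(fr)) agg$formation_rate_nm <- c(mean = mean(fr),
                                             sd = stats::sd(fr))
  cr <- grab("compaction_rate", "compaction")
  if (length(cr)) agg$compaction_rate <- c(mean = mean(cr),
                                           sd = stats::sd(cr))
  labels <- unlist(lapply(per, function(r) r$class_label))
  if (length(labels)) {
    counts <- table(labels)
    agg$class_counts <- counts
    agg$class_fractions <- lapply(as.list(counts), function(k)
      binomial_error(as.integer(k), length(labels)))
  }
  fits <- lapply(per, function(r) r$fit)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  ok <- vapply(fits, function(f) isTRUE(f$accepted), logical(1))
  if (any(ok)) {
    lp <- vapply(fits[ok], function(f) f$params$lp, numeric(1))
    lc <- vapply(fits[ok], function(f) f$params$lc, numeric(1))
    agg$wlc <- list(lp_mean = mean(lp), lp_sd = stats::sd(lp),
                    lc_mean = mean(lc), lc_sd = stats::sd(lc),
                    n_accepted = sum(ok), n_fitted = length(fits))
  }
  structure(list(per_trace = per, errors = errs, aggregates = agg,
                 stamp = config$stamp),
            class = "fm_report")
}

#' @export
print.fm_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("Cohort report: %d traces (%d failed)\n",
              a$n_traces %||% 0L, a$n_failed %||% 0L))
  if (!is.null(a$k_nucl))
    cat(sprintf("  nucleation rate: %.4g 1/s\n", a$k_nucl))
  if (!is.null(a$formation_rate_nm))
    cat(sprintf("  formation rate: %.4g +/- %.3g nm/s\n",
                a$formation_rate_nm[["mean"]], a$formation_rate_nm[["sd"]]))
  if (!is.null(a$compaction_rate))
    cat(sprintf("  compaction rate: %.4g +/- %.3g nm/s\n",
                a$compaction_rate[["mean"]], a$compaction_rate[["sd"]]))
  if (!is.null(a$class_counts)) {
    cat("  outcome classes: ",
        paste(sprintf("%s=%d", names(a$class_counts),
                      as.integer(a$class_counts)), collapse = ", "), "\n")
  }
  if (!is.null(a$wlc))
    cat(sprintf("  WLC (accepted %d/%d): Lp %.4g +/- %.3g nm, Lc %.5g +/- %.3g nm\n",
                a$wlc$n_accepted, a$wlc$n_fitted, a$wlc$lp_mean, a$wlc$lp_sd,
                a$wlc$lc_mean, a$wlc$lc_sd))
  invisible(x)
}
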
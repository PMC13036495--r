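# Trace segmentation and rate estimators.

test_that("moving-average filter is exact at its limits and shrinks noise", {
  tru <- ground_truth(k_nucl = 0, k_form = 0)
  tr <- simulate_assembly_trace(sim_config(duration = 30, noise_sd = 10,
                                           seed = 4), tru)
  expect_equal(lowpass(tr, 1)$extension, tr$extension)
  flat <- tr
  flat$extension <- rep(500, nrow(tr))
  expect_equal(lowpass(flat, 58)$extension, rep(500, nrow(tr)))
  # variance of a 58-sample mean
  big <- simulate_assembly_trace(sim_config(duration = 1800, noise_sd = 10,
                                            seed = 14), tru)
  sm <- lowpass(big, 58)$extension
  interior <- sm[100:(length(sm) - 100)]
  expect_lt(abs(sd(interior) - 10 / sqrt(58)) / (10 / sqrt(58)), 0.1)
})

test_that("nucleation is detected at a step and absent in flat traces", {
  tru <- ground_truth(k_nucl = 0, k_form = 0)
  cfg <- sim_config(duration = 200, flush_time = 20, noise_sd = 5, seed = 1)
  flat <- simulate_assembly_trace(cfg, tru)
  expect_true(is.na(detect_nucleation(flat)))
  # synthetic 100 nm step 50 s after the flush
  step <- flat
  step$extension <- step$extension + 100 * (step$time >= 70)
  t_nucl <- detect_nucleation(step)
  expect_lt(abs(t_nucl - 50), 2)
})

test_that("detected nucleation times track the generator's ground truth", {
  tru <- ground_truth()
  res <- vapply(1:20, function(i) {
    tr <- simulate_assembly_trace(
      sim_config(duration = 150, flush_time = 20, seed = 1000 + i), tru)
    c(detect_nucleation(tr), trace_meta(tr)$t_nucl)
  }, numeric(2))
  expect_false(anyNA(res[1, ]))
  # detection lags the true crossing by the threshold climb, never leads it
  lag <- res[1, ] - res[2, ]
  expect_true(all(lag > -1.5))
  expect_lt(mean(abs(lag)), 3)
})

test_that("formation slopes are exact on clean ramps, absent on flat noise", {
  tru <- ground_truth(k_nucl = 0, k_form = 0)
  cfg <- sim_config(duration = 120, flush_time = 20, noise_sd = 5, seed = 2)
  base <- simulate_assembly_trace(cfg, tru)
  # noiseless linear rise of 3 nm/s on top of a quiet baseline
  clean <- base
  clean$extension <- 418 + 3 * pmax(clean$time - 20, 0)
  # interior region: clear of the slope kink and the filter edges
  expect_equal(formation_rate(clean, c(30, 110), baseline_sd = 1), 3,
               tolerance = 1e-9)
  # flat noisy trace: every window fails the 2 sd net-increase gate
  expect_true(is.na(formation_rate(base, c(20, 120))))
})

test_that("monomer-rate normalization is exact arithmetic and linear", {
  expect_equal(monomer_rate(2.8, delta_l_300 = 314.9), 2, tolerance = 1e-12)
  expect_equal(monomer_rate(0, 314.9), 0)
  r1 <- monomer_rate(2.8, 314.9, footprint_bp = 14)
  r2 <- monomer_rate(2.8, 314.9, footprint_bp = 28)
  expect_equal(r1, 2 * r2)
  expect_error(monomer_rate(1, 0), "delta_l_300")
})

test_that("end-to-end formation rate recovers monomers per second", {
  tru <- ground_truth()  # 8 monomers/s
  delta <- invert_wlc(0.1, filament_params()) - invert_wlc(0.1, bare_params())
  rates <- vapply(1:15, function(i) {
    tr <- simulate_assembly_trace(
      sim_config(duration = 150, flush_time = 20, seed = 2000 + i), tru)
    reg <- propose_regions(tr)
    if (is.null(reg$formation)) return(NA_real_)
    monomer_rate(formation_rate(tr, reg$formation), delta)
  }, numeric(1))
  expect_rel(mean(rates, na.rm = TRUE), 8, 0.2)
})

test_that("compaction slopes honor the 0.1 nm/s detection limit", {
  tru0 <- ground_truth(k_nucl = 0, k_form = 0)
  cfg <- sim_config(duration = 200, force = 0.5, noise_sd = 0, seed = 3)
  base <- simulate_assembly_trace(cfg, tru0)
  ramp <- base
  ramp$extension <- 800 - 5 * ramp$time
  expect_equal(compaction_rate(ramp, c(5, 195)), 5, tolerance = 1e-9)
  slow <- base
  slow$extension <- 800 - 0.05 * slow$time
  expect_true(is.na(compaction_rate(slow, c(5, 195))))
})

test_that("compaction rate survives injected ruptures when masked", {
  tru <- ground_truth(rupture_rate = 2 / 150, rupture_size_nm = 50)
  est <- vapply(1:15, function(i) {
    cfg <- sim_config(duration = 220, force = 0.5, noise_sd = 20,
                      seed = 3000 + i)
    tr <- simulate_compaction_phase(cfg, tru, 800)
    rupt <- detect_ruptures(tr, baseline_sd = 8.9)
    t1 <- trace_meta(tr)$t_floor
    if (is.na(t1)) t1 <- max(tr$time)
    compaction_rate(tr, c(0, t1), ruptures = rupt$time)
  }, numeric(1))
  expect_rel(mean(est, na.rm = TRUE), 5, 0.15)
})

test_that("rupture detector finds injected jumps and ignores small ones", {
  tru <- ground_truth(k_nucl = 0, k_form = 0)
  cfg <- sim_config(duration = 250, force = 0.5, noise_sd = 5, seed = 11)
  tr <- simulate_assembly_trace(cfg, tru)
  bsd <- sd(tr$extension[tr$time < 20])
  # three jumps of 4 baseline sds, 60 s apart
  jumpy <- tr
  for (t0 in c(60, 120, 180))
    jumpy$extension <- jumpy$extension + 4 * bsd * (jumpy$time >= t0)
  ev <- detect_ruptures(jumpy, bsd)
  expect_equal(nrow(ev), 3L)
  expect_true(all(abs(ev$time - c(60, 120, 180)) <= 2.5))
  # a 1.5 sd jump stays below the 2 sd threshold
  small <- tr
  small$extension <- small$extension + 1.5 * bsd * (small$time >= 100)
  expect_equal(nrow(detect_ruptures(small, bsd)), 0L)
})

test_that("rupture detector false-positive rate on pure noise is low", {
  tru <- ground_truth(k_nucl = 0, k_form = 0)
  events <- vapply(1:30, function(i) {
    tr <- simulate_assembly_trace(
      sim_config(duration = 200, noise_sd = 20, seed = 5000 + i), tru)
    nrow(detect_ruptures(tr, baseline_sd = 20))
  }, numeric(1))
  expect_lte(sum(events), 3)  # <= 1 event per 10 traces
})

test_that("outcome classes are recovered and order-independent", {
  tru <- ground_truth()
  classes <- c("extended", "fully_compacted", "partially_compacted",
               "dissociated")
  labels <- character(0)
  truth <- character(0)
  k <- 0
  for (cl in classes) for (i in 1:5) {
    k <- k + 1
    tr <- simulate_classified_trace(
      sim_config(duration = 200, force = 1, noise_sd = 20, flush_time = 20,
                 seed = 7000 + k), tru, cl)
    labels <- c(labels, classify_trace(tr, trace_meta(tr)$bare_extension))
    truth <- c(truth, cl)
  }
  expect_gte(mean(labels == truth), 0.9)
  # classification is a pure function of the trace
  tr <- simulate_classified_trace(
    sim_config(duration = 200, force = 1, noise_sd = 20, flush_time = 20,
               seed = 7001), tru, "extended")
  expect_identical(classify_trace(tr, trace_meta(tr)$bare_extension),
                   classify_trace(tr, trace_meta(tr)$bare_extension))
})

test_that("an accepted post-run force-extension fit vetoes full compaction", {
  tru <- ground_truth()
  tr <- simulate_classified_trace(
    sim_config(duration = 200, force = 1, noise_sd = 20, flush_time = 20,
               seed = 7100), tru, "fully_compacted")
  bare <- trace_meta(tr)$bare_extension
  live_fit <- fit_wlc_integrated(make_curve(filament_params()))
  expect_identical(classify_trace(tr, bare), "fully_compacted")
  expect_false(classify_trace(tr, bare, post_fit = live_fit) ==
                 "fully_compacted")
})

test_that("coilability and turn slopes are recovered from rotation sweeps", {
  tru <- ground_truth(pos_turn_slope = 15, neg_turn_slope = 1)
  tr <- simulate_rotation_extension(
    sim_config(duration = 100, force = 4, noise_sd = 20, seed = 31), tru)
  ck <- coilability_check(tr)
  expect_true(ck$coilable)
  expect_lt(abs(ck$pos_slope - 15), 1)
  # symmetric high-force regime: 0.74 nm/turn positive slope
  tru8 <- ground_truth(pos_turn_slope = 0.74, neg_turn_slope = 1)
  tr8 <- simulate_rotation_extension(
    sim_config(duration = 100, force = 8, noise_sd = 20, seed = 32), tru8)
  ck8 <- coilability_check(tr8)
  expect_rel(ck8$pos_slope, 0.74, 0.1)
  # non-coilable tether: flat response, near-zero slopes
  trn <- simulate_rotation_extension(
    sim_config(duration = 100, force = 4, noise_sd = 20, seed = 33), tru,
    coilable = FALSE)
  ckn <- coilability_check(trn)
  expect_false(ckn$coilable)
  expect_lt(abs(ckn$pos_slope), 0.5)
})
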
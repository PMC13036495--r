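# Synthetic trace generator: determinism, noiseless mechanics, and the
# generating distributions of the stochastic ingredients.

test_that("identical seed and config give bit-identical traces", {
  tru <- ground_truth(rupture_rate = 0.02)
  cfg <- sim_config(duration = 60, flush_time = 10, seed = 123)
  a <- simulate_assembly_trace(cfg, tru)
  b <- simulate_assembly_trace(cfg, tru)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c1 <- simulate_compaction_phase(cfg, tru, 700)
  c2 <- simulate_compaction_phase(cfg, tru, 700)
  expect_identical(c1$extension, c2$extension)
  # a different seed changes the noise
  d <- simulate_assembly_trace(sim_config(duration = 60, flush_time = 10,
                                          seed = 124), tru)
  expect_false(identical(a$extension, d$extension))
})

test_that("no kinetics gives a flat noisy baseline at the bare extension", {
  tru <- ground_truth(k_nucl = 0, k_form = 0)
  cfg <- sim_config(duration = 30, noise_sd = 10, seed = 3)
  tr <- simulate_assembly_trace(cfg, tru)
  bare <- invert_wlc(0.1, wlc_params(45, 896))
  expect_lt(abs(mean(tr$extension) - bare), 1)
  expect_lt(abs(sd(tr$extension) - 10), 1)
})

test_that("noiseless saturated assembly ends at the full-filament extension", {
  tru <- ground_truth(k_nucl = 50, k_form = 50)
  cfg <- sim_config(duration = 40, force = 1, noise_sd = 0, seed = 9)
  tr <- simulate_assembly_trace(cfg, tru)
  expect_equal(tr$extension[nrow(tr)],
               invert_wlc(1, wlc_params(200, 896)), tolerance = 1e-9)
})

test_that("nucleation waiting times are exponential with the set rate", {
  tru <- ground_truth(k_nucl = 0.062)
  waits <- vapply(1:200, function(i) {
    tr <- simulate_assembly_trace(sim_config(duration = 2, seed = 4000 + i),
                                  tru)
    trace_meta(tr)$t_nucl
  }, numeric(1))
  se <- (1 / 0.062) / sqrt(200)
  expect_lt(abs(mean(waits) - 1 / 0.062), 3 * se)
})

test_that("noiseless compaction is a linear ramp reaching the floor on time", {
  tru <- ground_truth(k_comp = 5, lc = 1000, rupture_rate = 0)
  cfg <- sim_config(duration = 200, force = 0.5, noise_sd = 0, seed = 2)
  tr <- simulate_compaction_phase(cfg, tru, 800)  # floor at 100 nm
  expect_equal(trace_meta(tr)$t_floor, (800 - 100) / 5, tolerance = 1e-9)
  during <- tr$time < 140
  slopes <- diff(tr$extension[during]) / diff(tr$time[during])
  expect_equal(unname(range(slopes)), c(-5, -5), tolerance = 1e-6)
  expect_equal(tr$extension[nrow(tr)], 100, tolerance = 1e-9)
  expect_error(simulate_compaction_phase(cfg, tru, 50), "floor")
})

test_that("injected ruptures are a Poisson process and reduce floor noise", {
  tru <- ground_truth(k_comp = 0, rupture_rate = 0.05)
  counts <- vapply(1:200, function(i) {
    tr <- simulate_compaction_phase(
      sim_config(duration = 50, noise_sd = 0, seed = 4500 + i), tru, 700)
    length(trace_meta(tr)$rupture_times)
  }, numeric(1))
  lambda <- 0.05 * 50
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 200))
  # noise drops after the floor is reached
  tru2 <- ground_truth(k_comp = 20, rupture_rate = 0)
  tr <- simulate_compaction_phase(
    sim_config(duration = 60, force = 0.5, noise_sd = 20, seed = 8),
    tru2, 500)
  t_floor <- trace_meta(tr)$t_floor
  sd_before <- sd(tr$extension[tr$time < t_floor - 5] -
                    (500 - 20 * tr$time[tr$time < t_floor - 5]))
  sd_after <- sd(tr$extension[tr$time > t_floor + 5])
  expect_lt(sd_after, 0.4 * sd_before)
})

test_that("noiseless ramps lie exactly on the WLC manifold", {
  p <- bare_params()
  tr <- simulate_force_ramp(sim_config(duration = 10, seed = 1), p,
                            noise_sd = 0)
  expect_equal(wlc_force(tr$extension, p), tr$force, tolerance = 1e-9)
  expect_error(simulate_force_ramp(sim_config(duration = 10, seed = 1), p,
                                   f_range = c(-1, 8)), "forces")
})

test_that("sampled rupture forces match their Normal population", {
  tru <- ground_truth(rupture_force_mean = 20, rupture_force_sd = 4)
  fr <- vapply(1:200, function(i) {
    tr <- simulate_force_ramp(sim_config(duration = 1, seed = 7000 + i),
                              bare_params(), f_range = c(0.5, 50),
                              rupture = TRUE, truth = tru)
    trace_meta(tr)$rupture_force
  }, numeric(1))
  expect_lt(abs(mean(fr) - 20), 3 * 4 / sqrt(200))
  expect_lt(abs(sd(fr) - 4), 3 * 4 / sqrt(2 * 200))
})

test_that("rotation sweeps encode the asymmetric turn slopes", {
  tru <- ground_truth(pos_turn_slope = 15, neg_turn_slope = 1)
  tr <- simulate_rotation_extension(
    sim_config(duration = 60, force = 4, noise_sd = 0, seed = 6), tru)
  apex <- max(tr$extension)
  end_pos <- tr$extension[which.max(tr$turns)]
  expect_equal(apex - end_pos, 15 * 50, tolerance = 1)
  # non-coilable tether ignores turns
  tr2 <- simulate_rotation_extension(
    sim_config(duration = 60, force = 4, noise_sd = 0, seed = 6), tru,
    coilable = FALSE)
  expect_equal(diff(range(tr2$extension)), 0, tolerance = 1e-9)
})

test_that("a single-strand gap caps per-segment coverage", {
  # gap at 30%: whichever segment nucleates first plateaus at its own
  # fraction of the full coverage until the second segment nucleates
  tru <- ground_truth(k_nucl = 0.2, k_form = 100, gap_at = 0.3)
  cfg <- sim_config(duration = 120, noise_sd = 0, seed = 11)
  tr <- simulate_assembly_trace(cfg, tru)
  md <- trace_meta(tr)
  t1 <- min(md$t_nucl_segments)
  t2 <- max(md$t_nucl_segments)
  expect_gt(t2 - t1, 5)  # seed chosen so the plateau is observable
  first_frac <- md$segment_fractions[which.min(md$t_nucl_segments)]
  plateau <- tr$extension[tr$time > t1 + 2 & tr$time < t2]
  expected <- invert_wlc(0.1, wlc_params(coverage_lp(first_frac, 45, 200),
                                         896))
  expect_equal(unname(max(abs(plateau - expected))), 0, tolerance = 1e-6)
})

test_that("occupancy cohorts follow the Hill isotherm with binomial noise", {
  conc <- c(25, 50, 100, 150, 200, 300)
  pts <- simulate_occupancy_counts(conc, kd = 25, n = 1.8, n_all = 1e6,
                                   seed = 77)
  expect_equal(pts$alpha, hill_alpha(conc, 25, 1.8), tolerance = 0.01)
  # midpoint: true occupancy is exactly 1/2 at c = kd
  expect_equal(pts$alpha_true[1], 0.5)
  expect_error(simulate_occupancy_counts(conc, kd = -1, n = 1.8, 10), "kd")
})
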
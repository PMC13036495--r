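# Shared fixtures: canonical parameter sets and quick curve builders.

bare_params <- function() wlc_params(lp = 45, lc = 896)
filament_params <- function() wlc_params(lp = 200, lc = 896)

# noiseless force-extension curve sampled on a force grid
make_curve <- function(params, f_min = 0.1, f_max = 8, n = 2000) {
  force <- exp(seq(log(f_min), log(f_max), length.out = n))
  data.frame(extension = invert_wlc(force, params), force = force)
}

# simulated ramp as a plain curve data frame
ramp_curve <- function(params, noise_sd, seed, duration = 40,
                       f_range = c(0.1, 8)) {
  tr <- simulate_force_ramp(sim_config(duration = duration, seed = seed),
                            params, noise_sd = noise_sd, f_range = f_range)
  data.frame(extension = tr$extension, force = tr$force)
}

expect_rel <- function(value, target, tol) {
  expect_lt(abs(value - target) / abs(target), tol)
}
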
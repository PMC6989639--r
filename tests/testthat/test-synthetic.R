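test_that("identical seeds reproduce bit-identical datasets", {
  cfg <- simulation_config(n_time = 80, n_freq = 60, seed = 5)
  s1 <- simulate_spectra(cfg)
  s2 <- simulate_spectra(cfg)
  expect_identical(s1$spectra$intensities, s2$spectra$intensities)
  expect_identical(s1$truth$background_truth, s2$truth$background_truth)
  s3 <- simulate_spectra(simulation_config(n_time = 80, n_freq = 60,
                                           seed = 6))
  expect_false(identical(s1$spectra$intensities, s3$spectra$intensities))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(simulate_spectra(simulation_config(n_time = 20, n_freq = 60,
                                               signals = list(), seed = 1)))
  expect_identical(rnorm(3), before)
})

test_that("a noiseless signal-free matrix is pure background and annihilates", {
  cfg <- simulation_config(n_time = 200, n_freq = 100, signals = list(),
                           noise_sd = 0, cosmic_ray_rate = 0,
                           drift_speed = 0, seed = 8)
  sim <- simulate_spectra(cfg)
  x <- sim$spectra$intensities
  expect_equal(x, sim$truth$background_truth, tolerance = 1e-12)
  # constant shape within every block: removal leaves essentially nothing
  y <- remove_background(sim$spectra, 50, 50)$values
  expect_lt(max(abs(y)), 1e-9 * max(x))
})

test_that("noise on signal-free rows is recovered by the MAD estimator", {
  cfg <- simulation_config(n_time = 300, n_freq = 200, signals = list(),
                           noise_sd = 2, cosmic_ray_rate = 0, seed = 9)
  sim <- simulate_spectra(cfg)
  cs <- remove_background(sim$spectra, 50, 50)
  sds <- apply(cs$values, 1, function(r) as.numeric(estimate_noise_sd(r)))
  expect_lt(abs(median(sds) - 2) / 2, 0.15)
})

test_that("faster background drift leaves more residual energy at large time windows", {
  energy <- vapply(c(0, 1, 3), function(speed) {
    cfg <- simulation_config(n_time = 400, n_freq = 100, signals = list(),
                             noise_sd = 0, cosmic_ray_rate = 0,
                             drift_speed = speed, seed = 10)
    y <- remove_background(simulate_spectra(cfg)$spectra,
                           w_time = 200, w_freq = 50)$values
    sum(y^2)
  }, numeric(1))
  expect_lt(energy[1], 1e-12 * energy[2])
  expect_gt(energy[3], energy[2])
})

test_that("ground truth records supports and shapes consistent with the matrix", {
  sim <- simulate_spectra(simulation_config(seed = 11))
  truth <- sim$truth
  expect_length(truth$signal_times, 3L)
  for (k in 1:3) {
    expect_true(all(truth$signal_times[[k]] >= 1 &
                      truth$signal_times[[k]] <= 600))
    sup <- truth$signal_support[[k]]
    expect_gte(sum(sup$end - sup$start + 1L), 10)   # >= 10-channel support
    g <- truth$signal_shape[[k]]
    expect_true(all(g[sersignal:::.interval_channels(sup)] > 0.05))
  }
})

test_that("shifted replicates translate signals and supports coherently", {
  sim <- simulate_spectra(simulation_config(seed = 12))
  rep0 <- shifted_replicate(sim, 0, seed = 12)  # same seed, zero shift
  expect_identical(rep0$spectra$intensities, sim$spectra$intensities)

  rep5 <- shifted_replicate(sim, +5, seed = 77)
  for (k in 1:3) {
    s0 <- sim$truth$signal_support[[k]]
    s5 <- rep5$truth$signal_support[[k]]
    expect_equal(s5$start, s0$start + 5L, tolerance = 0)
    expect_equal(s5$end, s0$end + 5L, tolerance = 0)
  }
  expect_error(shifted_replicate(sim, 150, seed = 1), "n_freq / 4")
})

test_that("shifting a pure-background pair produces no detections in either", {
  cfg <- simulation_config(n_time = 200, n_freq = 120, signals = list(),
                           cosmic_ray_rate = 0, seed = 13)
  sim <- simulate_spectra(cfg)
  rep5 <- shifted_replicate(sim, +5, seed = 14)
  for (s in list(sim, rep5)) {
    det <- detect_signals(remove_background(s$spectra, 50, 40),
                          alpha = 3, beta = 0.01, gamma = 3)
    expect_length(det$detected_times, 0)
  }
})

test_that("invalid configurations are rejected with the offending fields listed", {
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(cosmic_ray_rate = -2), "cosmic_ray_rate")
  expect_error(
    simulation_config(signals = list(list(onset = 900, duration = 3,
                                          centers = 10, widths = 2,
                                          amplitude = 6))),
    "time window")
  expect_error(simulation_config(background_shapes = list(rep(1, 3))),
               "two profiles")
  expect_error(
    simulation_config(n_freq = 4e2,
                      background_shapes = list(rep(1, 400), rep(-1, 400))),
    "strictly positive")
})
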
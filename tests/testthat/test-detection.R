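test_that("noise SD estimation is the scaled median absolute value", {
  row <- rep(c(-1, 1), 400)
  k <- 1 / qnorm(0.75)                 # independent quantile evaluation
  expect_equal(as.numeric(estimate_noise_sd(row)), k, tolerance = 1e-12)

  z <- estimate_noise_sd(rep(0, 100))
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("the noise estimate resists signal channels", {
  set.seed(21)
  for (i in 1:10) {
    row <- rnorm(2000)
    s0 <- as.numeric(estimate_noise_sd(row))
    sparse <- row
    sparse[1:80] <- sparse[1:80] + 20     # 4% of channels at 20 sigma
    expect_lt(abs(as.numeric(estimate_noise_sd(sparse)) - s0) / s0, 0.10)
    # median breakdown: even just below half contamination the estimate is
    # bounded and does not grow with the signal amplitude
    heavy20 <- row; heavy20[1:960] <- heavy20[1:960] + 20
    heavy2k <- row; heavy2k[1:960] <- heavy2k[1:960] + 2000
    s20 <- as.numeric(estimate_noise_sd(heavy20))
    expect_lt(s20, 4)
    expect_equal(as.numeric(estimate_noise_sd(heavy2k)), s20,
                 tolerance = 1e-12)
  }
})

test_that("channel p-values follow the one-sided Gaussian tail", {
  expect_equal(channel_pvalues(c(-3, 0, -0.01), 1), c(1, 1, 1))
  expect_equal(channel_pvalues(1e-12, 1), 1, tolerance = 1e-9)
  expect_equal(channel_pvalues(1.959964, 1), 0.05, tolerance = 1e-4)
  # degenerate row: everything 1
  expect_equal(channel_pvalues(c(5, -2, 0.1), 0), c(1, 1, 1))
  # extreme signals clamp instead of underflowing to zero
  expect_gte(min(channel_pvalues(c(500, 1000), 1)), 1e-300)
})

test_that("FDR conversion equals the literal step-up and preserves order", {
  expect_equal(fdr_convert(0.037), 0.037)
  expect_equal(fdr_convert(rep(0.2, 8)), rep(0.2, 8))
  expect_equal(fdr_convert(c(0.01, 0.02, 0.03, 0.04)),
               naive_bh(c(0.01, 0.02, 0.03, 0.04)), tolerance = 1e-14)
  set.seed(22)
  for (i in 1:25) {
    p <- runif(60)
    f <- fdr_convert(p)
    expect_equal(f, naive_bh(p), tolerance = 1e-13)
    expect_true(all(f >= p))                         # BH dominance
    expect_true(all(diff(f[order(p)]) >= -1e-15))    # order preserved
  }
  expect_error(fdr_convert(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_convert(c(-0.1)), "\\[0, 1\\]")
})

test_that("bumps are maximal runs passing both cutoffs", {
  w <- 60
  row <- rep(0.1, w)
  row[10:14] <- 10                    # length-5 run
  row[20:21] <- 10                    # length-2 run
  fdr <- fdr_convert(channel_pvalues(row, 1))
  b <- find_bumps(row, 1, fdr, alpha = 3, beta = 0.01, gamma = 3)
  expect_equal(b$start, c(10L, 20L))
  expect_equal(b$length, c(5L, 2L))
  expect_true(attr(b, "signal_positive"))
  # no two bumps adjacent or overlapping
  expect_true(all(b$start[-1] > b$end[-nrow(b)] + 1L))

  # an isolated cosmic-ray-like spike never qualifies the spectrum
  ray <- rep(0.1, w); ray[30] <- 50
  fdr <- fdr_convert(channel_pvalues(ray, 1))
  b <- find_bumps(ray, 1, fdr, alpha = 3, beta = 0.01, gamma = 2)
  expect_equal(b$length, 1L)
  expect_false(attr(b, "signal_positive"))

  none <- find_bumps(rep(0.5, w), 1, rep(1, w), alpha = 3, beta = 0.01,
                     gamma = 3)
  expect_equal(nrow(none), 0L)
  expect_error(find_bumps(row, 1, fdr, gamma = 0), "gamma")
})

test_that("an all-zero matrix yields no detections and degenerate rows", {
  expect_warning(det <- detect_signals(matrix(0, 5, 10)), "degenerate")
  expect_length(det$detected_times, 0)
  expect_equal(det$degenerate_rows, 1:5)
  expect_true(all(det$pvalues == 1))
})

test_that("detections disappear, never appear, as cutoffs tighten", {
  set.seed(23)
  y <- matrix(rnorm(150 * 80), 150, 80)
  picks <- sample(150, 12)
  for (t in picks) y[t, 30:42] <- y[t, 30:42] + runif(1, 2, 8)
  base <- detect_signals(y, alpha = 2, beta = 0.1, gamma = 2)
  for (det2 in list(detect_signals(y, alpha = 3, beta = 0.1, gamma = 2),
                    detect_signals(y, alpha = 2, beta = 0.01, gamma = 2),
                    detect_signals(y, alpha = 2, beta = 0.1, gamma = 4))) {
    expect_true(all(det2$detected_times %in% base$detected_times))
  }
})

test_that("absolute and noise-relative magnitude cutoffs are both available", {
  row <- rep(c(-2, 2), 40)
  row[30:36] <- 9
  sigma <- as.numeric(estimate_noise_sd(row))   # ~ 2 / qnorm(0.75) ~ 2.97
  fdr <- fdr_convert(channel_pvalues(row, sigma))
  rel <- find_bumps(row, sigma, fdr, alpha = 4, beta = 0.05, gamma = 3)
  abs_ <- find_bumps(row, sigma, fdr, alpha = 4, beta = 0.05, gamma = 3,
                     alpha_absolute = TRUE)
  # alpha = 4 means > 4*sigma ~ 11.9 in the relative reading (9 fails) but
  # > 4 intensity units in the absolute reading (9 passes)
  expect_equal(nrow(rel), 0L)
  expect_true(attr(abs_, "signal_positive"))
})

test_that("detected bumps in a row are reported with min FDR and peak value", {
  set.seed(24)
  y <- matrix(rnorm(40 * 60), 40, 60)
  y[7, 20:28] <- y[7, 20:28] + 9
  det <- detect_signals(y)
  expect_true(7 %in% det$detected_times)
  b <- det$bumps[det$bumps$time_index == 7, ]
  expect_true(any(b$bump_length >= 3))
  expect_true(all(b$min_fdr < det$params$beta))
  expect_equal(max(b$peak_value), max(y[7, 20:28]))
})
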
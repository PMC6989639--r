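test_that("axis segmentation uses floor counts with the remainder absorbed", {
  g <- partition_blocks(250, 90, 100, 40)
  expect_equal(nrow(g$time_bounds), 2L)
  expect_equal(g$time_bounds$end - g$time_bounds$start + 1L, c(100L, 150L))
  expect_equal(nrow(g$freq_bounds), 2L)
  expect_equal(g$freq_bounds$end - g$freq_bounds$start + 1L, c(40L, 50L))

  one <- partition_blocks(100, 100, 100, 100)
  expect_equal(nrow(one$blocks), 1L)
  expect_equal(unlist(one$blocks[1, c("t_start", "t_end", "f_start", "f_end")],
                      use.names = FALSE), c(1L, 100L, 1L, 100L))

  expect_error(partition_blocks(50, 100, 60, 10), "w_time")
  expect_error(partition_blocks(50, 100, 10, 200), "w_freq")
})

test_that("blocks tile the matrix exactly once", {
  for (dims in list(c(250, 90, 100, 40), c(7, 5, 3, 2), c(20, 20, 20, 20))) {
    g <- do.call(partition_blocks, as.list(dims))
    cover <- matrix(0L, dims[1], dims[2])
    b <- g$blocks
    for (k in seq_len(nrow(b)))
      cover[b$t_start[k]:b$t_end[k], b$f_start[k]:b$f_end[k]] <-
        cover[b$t_start[k]:b$t_end[k], b$f_start[k]:b$f_end[k]] + 1L
    expect_true(all(cover == 1L))
  }
})

test_that("block background estimation matches the per-definition oracle", {
  # pure multiplicative fragment: estimated shape = shape / mean(shape)
  shape <- c(2, 1, 4, 3)
  frag <- outer(c(1, 5, 0.3), shape)
  bb <- estimate_block_background(frag)
  expect_equal(bb$shape, shape / mean(shape), tolerance = 1e-12)
  expect_equal(rowMeans(bb$scaled_fragments), rep(1, 3), tolerance = 1e-12)

  ones <- estimate_block_background(matrix(1, 4, 5))
  expect_equal(ones$shape, rep(1, 5))

  frag <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(10, 1, 1, 1))
  bb <- estimate_block_background(frag)
  scaled <- frag / c(2.5, 5, 3.25)
  expect_equal(bb$shape,
               apply(scaled, 2, naive_median), tolerance = 1e-14)

  expect_error(estimate_block_background(rbind(c(1, 2), c(0, 0))),
               "row 2")
})

test_that("scaled fragment rows average exactly one on random inputs", {
  set.seed(7)
  for (i in 1:20) {
    frag <- matrix(rexp(12 * 9) + 0.01, 12, 9)
    bb <- estimate_block_background(frag)
    expect_lt(max(abs(rowMeans(bb$scaled_fragments) - 1)), 1e-12)
  }
})

test_that("a pure multiplicative block is annihilated exactly", {
  set.seed(11)
  shape <- rexp(20) + 0.1
  ci <- rexp(15) + 0.05
  frag <- outer(ci, shape)
  bb <- estimate_block_background(frag)
  y <- remove_block_background(frag, bb, q = 40)
  expect_lt(max(abs(y)), 1e-9 * max(frag))
})

test_that("changing the percentile only shifts each row by a multiple of the shape", {
  set.seed(12)
  frag <- matrix(rexp(30 * 25) + 0.1, 30, 25)
  bb <- estimate_block_background(frag)
  y40 <- remove_block_background(frag, bb, q = 40)
  y50 <- remove_block_background(frag, bb, q = 50)
  d <- y40 - y50                      # rows must be multiples of the shape
  ratio <- d / rep(bb$shape, each = nrow(frag))
  expect_lt(max(abs(ratio - rowMeans(ratio))), 1e-9)
})

test_that("a narrow bump survives background removal in its own block", {
  set.seed(13)
  shape <- rexp(40) + 0.5
  frag <- outer(rexp(20) + 0.5, shape)
  bump_ch <- 10:17                    # 8 of 40 channels, well under 40%
  frag[9, bump_ch] <- frag[9, bump_ch] + 30 * exp(-(bump_ch - 13.5)^2 / 6)
  bb <- estimate_block_background(frag)
  y <- remove_block_background(frag, bb, q = 40)
  expect_gt(max(y[9, bump_ch]), 20)   # bump retained
  expect_lt(max(abs(y[9, -bump_ch])), 1e-6)  # bump-free channels near 0
  expect_lt(max(abs(y[-9, ])), 1e-6)
})

test_that("the division guard names a vanishing channel", {
  frag <- matrix(1, 5, 4)
  expect_error(remove_block_background(frag, c(1, 0, 1, 1), q = 40),
               "channel 2")
})

test_that("full background removal matches the literal triple-loop oracle", {
  set.seed(14)
  for (i in 1:5) {
    x <- matrix(rexp(24 * 18) + 0.05, 24, 18)
    cs <- remove_background(x, w_time = 10, w_freq = 5, q = 40)
    expect_equal(cs$values, naive_remove_background(x, 10, 5, 40),
                 tolerance = 1e-12)
  }
})

test_that("background removal is scale-equivariant", {
  set.seed(15)
  x <- matrix(rexp(40 * 30) + 0.1, 40, 30)
  y1 <- remove_background(x, 20, 10)$values
  y2 <- remove_background(7.5 * x, 20, 10)$values
  expect_equal(y2, 7.5 * y1, tolerance = 1e-12)
})

test_that("the median shape resists signals in fewer than half the rows", {
  set.seed(16)
  shape <- rexp(30) + 0.5
  frag <- outer(rep(1, 21), shape)
  clean <- estimate_block_background(frag)$shape
  corrupt <- frag
  corrupt[1:10, 5:12] <- corrupt[1:10, 5:12] + 50   # 10 of 21 rows
  dirty <- estimate_block_background(corrupt)$shape
  # the 11 clean rows outvote the corrupted ones at every channel: outside
  # the corrupted region the estimated shape is exactly unchanged
  expect_equal(dirty[-(5:12)], clean[-(5:12)], tolerance = 1e-12)
})

test_that("block errors are reported with block coordinates", {
  x <- matrix(1, 10, 10)
  x[7, ] <- 0                          # zero-mean row in block (2, 1)
  expect_error(remove_background(x, 5, 5), "block \\(2, 1\\)")
})
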
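#' Partition a spectra matrix into time-frequency blocks
#'
#' The background estimator works on rectangular blocks obtained by windowing
#' both the time axis and the frequency axis.  Each axis is cut into
#' `floor(n / w)` segments of length `w`; when `w` does not divide the axis
#' length, the remainder is absorbed into the final segment (whose length is
#' then between `w` and `2 w - 1`), so a 5,000 x 1,600 matrix windowed at
#' 100/100 gives exactly 50 x 16 blocks.
#'
#' @param n_time,n_freq matrix dimensions (time points, frequency channels).
#' @param w_time,w_freq window sizes along time and frequency; each must be
#'   between 1 and the corresponding dimension.
#' @return An object of class `block_grid`: list with `time_bounds` and
#'   `freq_bounds` (data.frames of segment `start`/`end` indices, 1-based
#'   closed) and `blocks`, a data.frame of all time x frequency segment
#'   combinations.
#' @export
#' @examples
#' g <- partition_blocks(5000, 1600, 100, 100)
#' nrow(g$time_bounds)   # 50
#' nrow(g$freq_bounds)   # 16
partition_blocks <- function(n_time, n_freq, w_time, w_freq) {
  n_time <- as.integer(n_time); n_freq <- as.integer(n_freq)
  w_time <- as.integer(w_time); w_freq <- as.integer(w_freq)
  if (w_time < 1L || w_time > n_time)
    stop(sprintf("w_time = %d outside [1, %d]", w_time, n_time))
  if (w_freq < 1L || w_freq > n_freq)
    stop(sprintf("w_freq = %d outside [1, %d]", w_freq, n_freq))
  tb <- .segment_axis(n_time, w_time)
  fb <- .segment_axis(n_freq, w_freq)
  blocks <- expand.grid(time_segment = seq_len(nrow(tb)),
                        freq_segment = seq_len(nrow(fb)),
                        KEEP.OUT.ATTRS = FALSE)
  blocks$t_start <- tb$start[blocks$time_segment]
  blocks$t_end <- tb$end[blocks$time_segment]
  blocks$f_start <- fb$start[blocks$freq_segment]
  blocks$f_end <- fb$end[blocks$freq_segment]
  structure(
    list(w_time = w_time, w_freq = w_freq,
         time_bounds = tb, freq_bounds = fb, blocks = blocks),
    class = "block_grid")
}

.segment_axis <- function(n, w) {
  k <- n %/% w
  start <- (seq_len(k) - 1L) * w + 1L
  end <- c(start[-1L] - 1L, n)   # final segment absorbs the remainder
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("<block_grid> %d time segments x %d frequency segments (w_time = %d, w_freq = %d)\n",
              nrow(x$time_bounds), nrow(x$freq_bounds), x$w_time, x$w_freq))
  invisible(x)
}

#' Estimate the background shape of one time-frequency block
#'
#' Each row (spectrum fragment) of the block is scaled by its mean, which
#' removes the per-time overall strength and keeps only the shape.  The
#' block's background shape is then the per-channel median of the scaled
#' fragments, taken independently for every channel: no smoothing is applied
#' along frequency, because a SERS background can change steeply from one
#' channel to the next.  The median makes the shape robust to analyte
#' signals present in fewer than half of the block's rows.
#'
#' @param fragment numeric matrix, the block's sub-matrix of raw
#'   intensities; every row must have a strictly positive mean.
#' @return An object of class `block_background`: list with `shape` (the
#'   per-channel median of the mean-scaled rows) and `scaled_fragments` (the
#'   mean-scaled rows, each averaging exactly 1).
#' @export
estimate_block_background <- function(fragment) {
  fragment <- as.matrix(fragment)
  rm <- rowMeans(fragment)
  bad <- which(rm <= 0)
  if (length(bad) > 0)
    stop(sprintf(
      "degenerate fragment: row %d has mean %g (must be > 0)",
      bad[1L], rm[bad[1L]]))
  scaled <- fragment / rm
  shape <- apply(scaled, 2L, stats::median)
  structure(list(shape = shape, scaled_fragments = scaled),
            class = "block_background")
}

#' Remove the estimated background from one block
#'
#' Every raw fragment row is divided channel-wise by the background shape,
#' giving a projection profile; its `q`-th percentile is the row's overall
#' scaling factor, and that multiple of the shape is subtracted from the raw
#' row.  Using a percentile below the median biases the scaling toward
#' background-only channels, so analyte bumps (which push the profile up on
#' a minority of channels) are preserved rather than subtracted away.
#'
#' @param fragment numeric matrix of raw intensities for the block.
#' @param background a [estimate_block_background()] result, or directly a
#'   numeric shape vector with one strictly positive entry per channel.
#' @param q percentile on the 0-100 scale (default 40) used as the per-row
#'   scaling factor; percentiles use linear interpolation between closest
#'   ranks.
#' @return Numeric matrix of corrected (signed) intensities, same shape as
#'   `fragment`.
#' @export
remove_block_background <- function(fragment, background, q = 40) {
  fragment <- as.matrix(fragment)
  shape <- if (inherits(background, "block_background")) background$shape
           else as.numeric(background)
  if (length(shape) != ncol(fragment))
    stop("background shape length does not match fragment width")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 100)
    stop("q must be a single percentile in (0, 100)")
  guard <- 1e-12 * mean(shape)
  small <- which(shape <= guard)
  if (length(small) > 0)
    stop(sprintf(
      "background shape vanishes at channel %d (value %g); cannot divide",
      small[1L], shape[small[1L]]))
  proj <- fragment / rep(shape, each = nrow(fragment))
  qi <- apply(proj, 1L, stats::quantile, probs = q / 100,
              type = 7, names = FALSE)
  fragment - outer(qi, shape)
}

#' Remove a time-varying background from a spectra matrix
#'
#' Background removal for time series of SERS spectra whose background
#' strength changes arbitrarily from spectrum to spectrum and whose shape
#' drifts slowly in time.  The matrix is partitioned into time-frequency
#' blocks ([partition_blocks()]); within each block the background shape is
#' the per-channel median of mean-scaled spectrum fragments
#' ([estimate_block_background()]), and each fragment's projection onto that
#' shape is subtracted ([remove_block_background()]).  Blocks are processed
#' independently, with no blending across block edges.
#'
#' Window sizes trade off tracking speed against signal preservation: the
#' faster the background changes with time, the smaller the windows should
#' be.  Overly large windows leave residual background; overly small ones
#' can remove part of long-lasting signals.  The defaults (50/50) suit
#' chromatographic SERS runs with short-lived analyte signals; for signals
#' lasting on the order of a hundred time points a larger time window
#' (e.g. 150) is appropriate.
#'
#' @param m a [spectra_matrix()] or a non-negative numeric matrix
#'   (time points x channels).
#' @param w_time,w_freq window sizes in time points and channels
#'   (defaults 50 and 50).
#' @param q percentile (0-100 scale, default 40) for the per-spectrum
#'   scaling factor; see [remove_block_background()].
#' @return A [corrected_spectra()] of the same shape, with `params`
#'   recording `w_time`, `w_freq` and `q`.
#' @export
#' @examples
#' sim <- simulate_spectra(simulation_config(n_time = 120, n_freq = 80,
#'                                           signals = list(), seed = 1))
#' cs <- remove_background(sim$spectra, w_time = 30, w_freq = 20)
#' range(cs$values)
remove_background <- function(m, w_time = 50, w_freq = 50, q = 40) {
  if (!inherits(m, "spectra_matrix")) m <- spectra_matrix(m)
  x <- m$intensities
  grid <- partition_blocks(nrow(x), ncol(x), w_time, w_freq)
  y <- matrix(0, nrow(x), ncol(x))
  b <- grid$blocks
  for (k in seq_len(nrow(b))) {
    ti <- b$t_start[k]:b$t_end[k]
    fi <- b$f_start[k]:b$f_end[k]
    frag <- x[ti, fi, drop = FALSE]
    y[ti, fi] <- tryCatch({
      bb <- estimate_block_background(frag)
      remove_block_background(frag, bb, q = q)
    }, error = function(e) {
      stop(sprintf(
        "block (%d, %d) [times %d-%d, channels %d-%d]: %s",
        b$time_segment[k], b$freq_segment[k],
        b$t_start[k], b$t_end[k], b$f_start[k], b$f_end[k],
        conditionMessage(e)), call. = FALSE)
    })
  }
  corrected_spectra(y, wavenumber = m$wavenumber,
                    params = list(w_time = grid$w_time, w_freq = grid$w_freq,
                                  q = q))
}
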
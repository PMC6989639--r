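#' Robust noise standard deviation of a corrected spectrum
#'
#' After background removal, noise fluctuates around zero while analyte
#' signals occupy a minority of channels.  The noise scale is therefore
#' estimated from the median absolute value of the corrected intensities,
#' rescaled by `1 / qnorm(0.75)` so that the estimate is consistent for the
#' standard deviation of Gaussian noise.  With its 50% breakdown point the
#' estimator is essentially unaffected by signals covering fewer than half
#' of the channels.
#'
#' @param row numeric vector, one background-corrected spectrum.
#' @return The estimated noise SD (a single non-negative number).  An
#'   all-zero row returns 0 with attribute `degenerate = TRUE`; downstream
#'   p-values for such a row are defined as 1.
#' @export
estimate_noise_sd <- function(row) {
  if (length(row) < 2L) stop("need at least 2 channels to estimate noise")
  k <- 1 / stats::qnorm(0.75)
  s <- k * stats::median(abs(row))
  if (s == 0) attr(s, "degenerate") <- TRUE
  s
}

#' Per-channel one-sided p-values for a corrected spectrum
#'
#' Analyte signals are positive excursions, so only positive corrected
#' intensities can be significant: for `y > 0` the p-value is the two-sided
#' Gaussian tail `2 * pnorm(-y / sigma)`, and non-positive channels get
#' p = 1.  P-values are clamped below at 1e-300 so that extreme signals do
#' not underflow to exact zeros.
#'
#' @param row numeric vector, one background-corrected spectrum.
#' @param sigma noise SD for the row, typically from [estimate_noise_sd()].
#'   If 0 (degenerate row), every p-value is 1.
#' @return Numeric vector of p-values in (0, 1].
#' @export
channel_pvalues <- function(row, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  p <- rep(1, length(row))
  if (sigma > 0) {
    pos <- row > 0
    p[pos] <- 2 * stats::pnorm(-row[pos] / sigma)
    p <- pmax(p, 1e-300)
  }
  p
}

#' Convert a spectrum's p-values to false discovery rates
#'
#' Benjamini-Hochberg step-up adjustment applied within a single spectrum
#' across its channels.  Adjusted values dominate the raw p-values, preserve
#' their order, and are clipped at 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values (per-channel FDR) in \[0, 1\].
#' @export
fdr_convert <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Find bumps in one corrected spectrum
#'
#' A bump is a maximal run of consecutive channels on which the corrected
#' intensity exceeds the magnitude cutoff and the per-channel FDR falls
#' below `beta`.  By default the magnitude cutoff is `alpha` noise SDs
#' (`row > alpha * sigma`), tying practical significance to the noise level;
#' set `alpha_absolute = TRUE` to read `alpha` as an absolute intensity
#' cutoff instead.
#'
#' @param row numeric vector, one background-corrected spectrum.
#' @param sigma noise SD of the row.
#' @param fdr_row per-channel FDR values for the row, from [fdr_convert()].
#' @param alpha magnitude cutoff, in noise-SD units by default (default 3).
#' @param beta FDR cutoff (default 0.05).
#' @param gamma minimum bump length, in channels, for the row to count as
#'   carrying signal (default 3); single-channel spikes such as cosmic rays
#'   fail this cutoff.
#' @param alpha_absolute if `TRUE`, `alpha` is an absolute intensity.
#' @return A data.frame of bumps with columns `start`, `end`, `length`,
#'   `peak_value` and `min_fdr`, plus attribute `signal_positive`, `TRUE`
#'   when some bump has length `>= gamma`.
#' @export
find_bumps <- function(row, sigma, fdr_row, alpha = 3, beta = 0.05,
                       gamma = 3, alpha_absolute = FALSE) {
  if (length(fdr_row) != length(row))
    stop("row and fdr_row must have the same length")
  if (gamma < 1) stop("gamma must be >= 1")
  cut <- if (alpha_absolute) alpha else alpha * sigma
  qual <- (row > cut) & (fdr_row < beta)
  bumps <- .runs_to_bumps(qual, row, fdr_row)
  attr(bumps, "signal_positive") <-
    nrow(bumps) > 0 && max(bumps$length) >= gamma
  bumps
}

.runs_to_bumps <- function(qual, row, fdr_row) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), peak_value = numeric(0),
                      min_fdr = numeric(0)))
  data.frame(
    start = as.integer(starts), end = as.integer(ends),
    length = as.integer(ends - starts + 1L),
    peak_value = vapply(seq_along(starts), function(k)
      max(row[starts[k]:ends[k]]), numeric(1)),
    min_fdr = vapply(seq_along(starts), function(k)
      min(fdr_row[starts[k]:ends[k]]), numeric(1)))
}

#' Detect analyte signals in background-corrected spectra
#'
#' Applies the three-stage per-spectrum filter to every row: robust noise SD
#' ([estimate_noise_sd()]), Gaussian tail p-values converted to per-channel
#' FDR ([channel_pvalues()], [fdr_convert()]), and bump finding with
#' magnitude, FDR and run-length cutoffs ([find_bumps()]).  A time point is
#' detected when its spectrum has at least one bump of length `>= gamma`.
#'
#' @param cs a [corrected_spectra()] (or a numeric matrix of corrected
#'   intensities).
#' @param alpha magnitude cutoff in noise-SD units (default 3); see
#'   `alpha_absolute`.
#' @param beta FDR cutoff (default 0.05).
#' @param gamma minimum bump length in channels (default 3).
#' @param alpha_absolute if `TRUE`, `alpha` is an absolute intensity cutoff.
#' @return An object of class `detection_result`: list with
#'   `detected_times` (sorted integer vector), `bumps` (data.frame with
#'   columns `time_index`, `bump_start`, `bump_end`, `bump_length`,
#'   `peak_value`, `min_fdr`, rows only for detected times), `noise_sd`
#'   (per-row SD), `pvalues` and `fdr_values` (matrices), `degenerate_rows`
#'   and `params`.
#' @export
#' @examples
#' y <- matrix(rnorm(200 * 50), 200, 50)
#' y[100, 20:32] <- y[100, 20:32] + 8     # one injected bump
#' det <- detect_signals(corrected_spectra(y))
#' det$detected_times
detect_signals <- function(cs, alpha = 3, beta = 0.05, gamma = 3,
                           alpha_absolute = FALSE) {
  if (!inherits(cs, "corrected_spectra")) cs <- corrected_spectra(cs)
  y <- cs$values
  n_time <- nrow(y); n_freq <- ncol(y)
  k <- 1 / stats::qnorm(0.75)
  sigma <- k * apply(abs(y), 1L, stats::median)
  degenerate <- which(sigma == 0)
  if (length(degenerate) > 0)
    warning(sprintf("%d degenerate row(s) with zero noise estimate (e.g. time %d); their p-values are 1",
                    length(degenerate), degenerate[1L]))

  p <- matrix(1, n_time, n_freq)
  live <- sigma > 0
  if (any(live)) {
    z <- y[live, , drop = FALSE] / sigma[live]
    pl <- matrix(1, sum(live), n_freq)
    pos <- z > 0
    pl[pos] <- pmax(2 * stats::pnorm(-z[pos]), 1e-300)
    p[live, ] <- pl
  }
  f <- t(apply(p, 1L, stats::p.adjust, method = "BH"))

  cut <- if (alpha_absolute) rep(alpha, n_time) else alpha * sigma
  qual <- (y > cut) & (f < beta)
  cand <- which(rowSums(qual) > 0)
  bump_rows <- vector("list", length(cand))
  detected <- logical(length(cand))
  for (i in seq_along(cand)) {
    t_i <- cand[i]
    b <- .runs_to_bumps(qual[t_i, ], y[t_i, ], f[t_i, ])
    detected[i] <- max(b$length) >= gamma
    if (detected[i])
      bump_rows[[i]] <- data.frame(time_index = t_i,
                                   bump_start = b$start, bump_end = b$end,
                                   bump_length = b$length,
                                   peak_value = b$peak_value,
                                   min_fdr = b$min_fdr)
  }
  bumps <- if (any(detected)) do.call(rbind, bump_rows[detected])
           else data.frame(time_index = integer(0), bump_start = integer(0),
                           bump_end = integer(0), bump_length = integer(0),
                           peak_value = numeric(0), min_fdr = numeric(0))
  rownames(bumps) <- NULL
  structure(
    list(detected_times = as.integer(cand[detected]),
         bumps = bumps, noise_sd = sigma,
         pvalues = p, fdr_values = f,
         degenerate_rows = as.integer(degenerate),
         params = list(alpha = alpha, beta = beta, gamma = gamma,
                       alpha_absolute = alpha_absolute)),
    class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d detected time point(s), %d bump(s)\n",
              length(x$detected_times), nrow(x$bumps)))
  cat("  parameters:", paste(names(x$params), unlist(x$params),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}
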
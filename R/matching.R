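#' Shift-tolerant similarity of two signature signals
#'
#' Small wavenumber-calibration differences between experiments shift a
#' signal by a few frequency channels, which can destroy a naive Pearson
#' correlation between otherwise identical signals.  The metric therefore
#' translates the second signal by every integer number of channels `s` in
#' `[-max_shift, +max_shift]`, recomputes the informative section (union of
#' the first signal's support and the translated support of the second,
#' clipped to the channel range), evaluates the Pearson correlation over
#' the section's channels, and reports the largest correlation found.
#'
#' Recorded supports are the detector's bump intervals, which capture only
#' the channels where a peak exceeds the detection cutoffs; the frequency
#' range a signal actually occupies extends a few channels further down
#' each flank.  Each support interval is therefore widened by
#' `support_pad` channels on both sides before the union is formed, so the
#' section includes the flanks that give the correlation its shape
#' contrast (over the supra-threshold crest alone, two matching peaks look
#' like flat plateaus and correlate poorly).
#'
#' Positive `s` moves the second signal toward higher channel indices, so a
#' signal recorded `d` channels too high is matched at `s = -d`.  Shifts
#' whose section retains fewer than 3 usable channels are skipped (a
#' correlation on fewer points is degenerate); ties in correlation are
#' broken toward the smallest `|s|`, then the smaller `s`.
#'
#' @param sig_a,sig_b [signature_signal()] objects on the same channel
#'   grid.
#' @param max_shift maximum |shift| searched, in channels (default 10;
#'   calibration shifts are typically smaller than ten channels).
#' @param support_pad channels added to each side of every support
#'   interval before forming the section (default 5, about one peak
#'   half-width); 0 restricts the section to the bump channels themselves.
#' @return An object of class `match_result`: list with `best_shift`,
#'   `best_correlation`, `correlation_at_zero` (NA if the unshifted section
#'   was degenerate) and `informative_section` (the section at the best
#'   shift).
#' @export
shifted_similarity <- function(sig_a, sig_b, max_shift = 10,
                               support_pad = 5) {
  w <- length(sig_a$spectrum)
  if (length(sig_b$spectrum) != w)
    stop("signals live on different channel grids")
  max_shift <- as.integer(max_shift)
  if (max_shift < 0 || max_shift >= w / 2)
    stop("max_shift must satisfy 0 <= max_shift < W/2")
  if (support_pad < 0) stop("support_pad must be >= 0")
  sup_a <- .pad_intervals(sig_a$support, support_pad, w)
  sup_b0 <- .pad_intervals(sig_b$support, support_pad, w)

  # visit shifts by increasing |s| (negative first) so that keeping the
  # first strict maximum implements the tie-break: smallest |s|, then
  # smaller s
  shifts <- order(abs(seq(-max_shift, max_shift)),
                  seq(-max_shift, max_shift))
  shifts <- seq(-max_shift, max_shift)[shifts]

  best <- NULL
  cor0 <- NA_real_
  for (s in shifts) {
    sup_b <- .shift_intervals(sup_b0, s, w)
    if (nrow(sup_b) == 0L) next
    section <- .coalesce_intervals(rbind(sup_a, sup_b))
    ch <- .interval_channels(section)
    # channels where the translated second signal is defined
    ch <- ch[ch - s >= 1L & ch - s <= w]
    if (length(ch) < 3L) next
    a_vals <- sig_a$spectrum[ch]
    b_vals <- sig_b$spectrum[ch - s]
    r <- .safe_cor(a_vals, b_vals, sprintf("shift %d", s))
    if (s == 0L) cor0 <- r
    if (is.null(best) || r > best$best_correlation)
      best <- list(best_shift = s, best_correlation = r,
                   informative_section = section)
  }
  if (is.null(best))
    stop("signals have no usable channel overlap at any shift")
  best$correlation_at_zero <- cor0
  structure(best[c("best_shift", "best_correlation", "correlation_at_zero",
                   "informative_section")],
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> best shift %+d, correlation %.4f (unshifted %.4f)\n",
    x$best_shift, x$best_correlation,
    if (is.na(x$correlation_at_zero)) NaN else x$correlation_at_zero))
  cat("  informative section:", .format_intervals(x$informative_section),
      "\n")
  invisible(x)
}

#' Match signature signals across two experiments
#'
#' Scores every pair of signature signals from two experiments with
#' [shifted_similarity()] and reports the pairs whose best correlation
#' reaches `min_similarity`, sorted by decreasing correlation.
#'
#' @param list_a,list_b lists of [signature_signal()] objects (e.g. from
#'   [merge_signals()]) from the two experiments.
#' @param max_shift maximum |shift| searched per pair (default 10).
#' @param min_similarity minimum best correlation for a pair to be
#'   reported (default 0.5).
#' @param support_pad flank padding of support intervals, in channels;
#'   see [shifted_similarity()].
#' @return A data.frame with columns `a_time`, `b_time`, `best_shift`,
#'   `best_correlation`, `correlation_at_zero` and `section`, sorted by
#'   decreasing `best_correlation`.
#' @export
match_signatures <- function(list_a, list_b, max_shift = 10,
                             min_similarity = 0.5, support_pad = 5) {
  if (length(list_a) == 0L || length(list_b) == 0L)
    stop("both signature lists must be non-empty")
  rows <- list()
  for (i in seq_along(list_a)) {
    for (j in seq_along(list_b)) {
      mr <- tryCatch(
        shifted_similarity(list_a[[i]], list_b[[j]], max_shift = max_shift,
                           support_pad = support_pad),
        error = function(e) e)
      if (inherits(mr, "error")) {
        warning(sprintf("pair (%d, %d) not scored: %s", i, j,
                        conditionMessage(mr)))
        next
      }
      if (mr$best_correlation >= min_similarity)
        rows[[length(rows) + 1L]] <- data.frame(
          a_time = list_a[[i]]$time_index,
          b_time = list_b[[j]]$time_index,
          best_shift = mr$best_shift,
          best_correlation = mr$best_correlation,
          correlation_at_zero = mr$correlation_at_zero,
          section = .format_intervals(mr$informative_section))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(a_time = integer(0), b_time = integer(0),
                      best_shift = integer(0), best_correlation = numeric(0),
                      correlation_at_zero = numeric(0),
                      section = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$best_correlation, out$a_time, out$b_time), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
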
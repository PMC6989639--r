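#' Strength of a detected signal
#'
#' The strength of a detected spectrum is the median of the absolute
#' corrected intensity over the channels of its bump support.  Restricting
#' the median to the support keeps the statistic about the signal itself;
#' over all channels it would be dominated by noise.
#'
#' @param row numeric vector, one background-corrected spectrum.
#' @param support channel support: interval `data.frame` (`start`/`end`),
#'   two-column matrix, or `c(start, end)` vector; 1-based closed.
#' @return The signal strength (non-negative scalar).
#' @export
signal_strength <- function(row, support) {
  iv <- .as_intervals(support, "support")
  ch <- .interval_channels(iv)
  if (length(ch) == 0L) stop("support is empty")
  if (max(ch) > length(row) || min(ch) < 1L)
    stop("support exceeds the spectrum's channel range")
  stats::median(abs(row[ch]))
}

#' Construct a signature signal
#'
#' A signature signal is the single spectrum retained for one analyte
#' event: the corrected spectrum at the surviving time point together with
#' the bump support on which it was detected.
#'
#' @param time_index 1-based time point of the retained spectrum.
#' @param spectrum numeric vector, the corrected spectrum at that time.
#' @param support interval `data.frame`/matrix/vector of bump channels.
#' @param strength optional precomputed strength; computed with
#'   [signal_strength()] when omitted.
#' @return An object of class `signature_signal`.
#' @export
signature_signal <- function(time_index, spectrum, support, strength = NULL) {
  iv <- .coalesce_intervals(.as_intervals(support, "support"))
  if (is.null(strength)) strength <- signal_strength(spectrum, iv)
  structure(
    list(time_index = as.integer(time_index), spectrum = as.numeric(spectrum),
         support = iv, strength = as.numeric(strength)),
    class = "signature_signal")
}

#' @export
print.signature_signal <- function(x, ...) {
  cat(sprintf("<signature_signal> time %d, strength %.4g, support %s\n",
              x$time_index, x$strength, .format_intervals(x$support)))
  invisible(x)
}

.format_intervals <- function(iv) {
  paste(sprintf("%d-%d", iv$start, iv$end), collapse = ";")
}

.parse_intervals <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  m <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
  data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]))
}

# Pearson correlation with the degenerate case pinned down: a zero-variance
# vector carries no shape information, so the pair is treated as dissimilar.
.safe_cor <- function(a, b, context = "correlation") {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning(context, ": zero-variance spectrum; correlation taken as 0")
    return(0)
  }
  stats::cor(a, b)
}

#' Merge runs of consecutive, similar detections into signature signals
#'
#' An analyte event typically spans several consecutive time points whose
#' spectra share one shape at varying strength (the signal intensifies,
#' then fades).  Detections are walked in time order, comparing each
#' detected time only with its immediate predecessor: if the two are
#' consecutive (`t_k = t_{k-1} + 1`) and the Pearson correlation of their
#' full corrected spectra exceeds `phi`, they belong to the same event and
#' only the stronger one survives; otherwise a new event starts.  Within an
#' event the surviving time is updated whenever a spectrum is stronger than
#' its immediate predecessor (ties keep the earlier time), which for
#' rise-and-fade intensity profiles retains the time of maximal strength.
#'
#' @param cs the [corrected_spectra()] the detections came from.
#' @param det a [detect_signals()] result (only `detected_times` and
#'   `bumps` are used).
#' @param phi similarity threshold in (-1, 1); default 0.9, high enough
#'   that distinct co-eluting analytes are not merged.
#' @return A list of [signature_signal()] objects, ordered by time, with
#'   class `signature_list`.
#' @export
merge_signals <- function(cs, det, phi = 0.9) {
  if (!inherits(cs, "corrected_spectra")) cs <- corrected_spectra(cs)
  if (!is.numeric(phi) || length(phi) != 1L || phi <= -1 || phi >= 1)
    stop("phi must be a single number in (-1, 1)")
  times <- sort(as.integer(det$detected_times))
  y <- cs$values
  if (any(times < 1L | times > nrow(y)))
    stop("detected times outside the corrected matrix")
  out <- list()
  if (length(times) == 0L)
    return(structure(out, class = "signature_list"))

  sig_at <- function(t) {
    b <- det$bumps[det$bumps$time_index == t, , drop = FALSE]
    if (nrow(b) == 0L)
      stop(sprintf("no bump support recorded for detected time %d", t))
    signature_signal(t, y[t, ],
                     data.frame(start = b$bump_start, end = b$bump_end))
  }

  rep_sig <- sig_at(times[1L])       # current event's surviving signal
  prev_strength <- rep_sig$strength  # strength of the immediate predecessor
  if (length(times) > 1L) {
    for (k in 2L:length(times)) {
      t_k <- times[k]
      t_prev <- times[k - 1L]
      cur <- sig_at(t_k)
      same_event <- (t_k == t_prev + 1L) &&
        .safe_cor(y[t_prev, ], y[t_k, ],
                  sprintf("merging times %d/%d", t_prev, t_k)) > phi
      if (same_event) {
        if (cur$strength > prev_strength) rep_sig <- cur
      } else {
        out[[length(out) + 1L]] <- rep_sig
        rep_sig <- cur
      }
      prev_strength <- cur$strength
    }
  }
  out[[length(out) + 1L]] <- rep_sig
  structure(out, class = "signature_list")
}

#' @export
print.signature_list <- function(x, ...) {
  cat(sprintf("<signature_list> %d signature signal(s)\n", length(x)))
  for (s in x)
    cat(sprintf("  time %d  strength %.4g  support %s\n",
                s$time_index, s$strength, .format_intervals(s$support)))
  invisible(x)
}

#' @export
as.data.frame.signature_list <- function(x, ...) {
  data.frame(
    time_index = vapply(x, `[[`, integer(1), "time_index"),
    support = vapply(x, function(s) .format_intervals(s$support),
                     character(1)),
    strength = vapply(x, `[[`, numeric(1), "strength"))
}
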
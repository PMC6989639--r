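# Closed 1-based channel intervals, represented as a data.frame with integer
# columns `start` and `end`, start <= end. These are the currency for bump
# supports and informative sections.

.as_intervals <- function(x, what = "interval set") {
  if (is.null(x)) stop(what, " is empty")
  if (is.data.frame(x)) {
    if (!all(c("start", "end") %in% names(x)))
      stop(what, " must have columns 'start' and 'end'")
    iv <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  } else if (is.matrix(x)) {
    if (ncol(x) != 2L) stop(what, " matrix must have two columns")
    iv <- data.frame(start = as.integer(x[, 1L]), end = as.integer(x[, 2L]))
  } else if (is.numeric(x)) {
    if (length(x) != 2L)
      stop(what, " vector must be c(start, end)")
    iv <- data.frame(start = as.integer(x[1L]), end = as.integer(x[2L]))
  } else {
    stop("cannot interpret ", what)
  }
  if (nrow(iv) == 0L) stop(what, " is empty")
  if (anyNA(iv)) stop(what, " contains missing endpoints")
  if (any(iv$end < iv$start))
    stop(what, " has an interval with end < start")
  iv
}

# Sort and coalesce overlapping or adjacent (end + 1 >= next start) intervals.
.coalesce_intervals <- function(iv) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  if (nrow(iv) <= 1L) {
    rownames(iv) <- NULL
    return(iv)
  }
  starts <- iv$start[1L]
  ends <- iv$end[1L]
  for (k in 2L:nrow(iv)) {
    n <- length(starts)
    if (iv$start[k] <= ends[n] + 1L) {
      ends[n] <- max(ends[n], iv$end[k])
    } else {
      starts <- c(starts, iv$start[k])
      ends <- c(ends, iv$end[k])
    }
  }
  data.frame(start = starts, end = ends)
}

.pad_intervals <- function(iv, pad, w) {
  iv$start <- pmax(iv$start - as.integer(pad), 1L)
  iv$end <- pmin(iv$end + as.integer(pad), as.integer(w))
  .coalesce_intervals(iv)
}

.shift_intervals <- function(iv, s, w) {
  iv$start <- iv$start + s
  iv$end <- iv$end + s
  iv$start <- pmax(iv$start, 1L)
  iv$end <- pmin(iv$end, as.integer(w))
  iv <- iv[iv$start <= iv$end, , drop = FALSE]
  rownames(iv) <- NULL
  iv
}

.interval_channels <- function(iv) {
  if (nrow(iv) == 0L) return(integer(0))
  sort(unique(unlist(mapply(seq.int, iv$start, iv$end, SIMPLIFY = FALSE))))
}

#' Informative section of two signal supports
#'
#' When two signals are compared, only the channels where at least one of
#' them occupies carry information about their shapes; the rest is noise.
#' The informative section is the union of the two supports, with
#' overlapping or directly adjacent intervals coalesced.  For instance,
#' supports covering channels 400-600 and 500-650 give the single section
#' 400-650.
#'
#' @param support_a,support_b channel supports: a `data.frame` with columns
#'   `start`/`end`, a two-column matrix, or a length-2 vector `c(start, end)`;
#'   1-based closed intervals.
#' @return A `data.frame` with columns `start` and `end`, sorted, disjoint
#'   and non-adjacent.
#' @export
#' @examples
#' informative_section(c(400, 600), c(500, 650))
#' informative_section(c(100, 200), c(300, 400))
informative_section <- function(support_a, support_b) {
  a <- .as_intervals(support_a, "support_a")
  b <- .as_intervals(support_b, "support_b")
  .coalesce_intervals(rbind(a, b))
}
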
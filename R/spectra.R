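#' Construct a spectra matrix
#'
#' A `spectra_matrix` holds a time series of Raman/SERS spectra as a numeric
#' matrix with one spectrum (time point) per row and one frequency channel per
#' column.  Raw detector intensities are physical counts and must be
#' non-negative and finite.  An optional wavenumber axis annotates the
#' columns; all computations operate on the channel index, so the axis is
#' annotation only.
#'
#' @param intensities numeric matrix, `T` time points x `W` frequency
#'   channels, all values finite and `>= 0`.
#' @param wavenumber optional numeric vector of length `W`, strictly
#'   increasing (cm^-1).  Defaults to the channel index `1:W`.
#' @param time_index integer vector of length `T`, the 1-based acquisition
#'   index of each row.
#'
#' @return An object of class `spectra_matrix` with elements `intensities`,
#'   `wavenumber` and `time_index`.
#' @seealso [read_spectra()], [remove_background()], [simulate_spectra()]
#' @export
#' @examples
#' m <- spectra_matrix(matrix(1:6, nrow = 2), wavenumber = c(400, 410, 420))
#' dim(m)
spectra_matrix <- function(intensities, wavenumber = NULL,
                           time_index = seq_len(nrow(intensities))) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) < 1L || ncol(intensities) < 1L)
    stop("intensities must have at least one row and one column")
  .check_finite(intensities, "intensities")
  neg <- which(intensities < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf(
      "negative intensity %g at row %d, column %d; raw spectra must be >= 0",
      intensities[neg[1, 1], neg[1, 2]], neg[1, 1], neg[1, 2]))
  wavenumber <- .check_wavenumber(wavenumber, ncol(intensities))
  if (length(time_index) != nrow(intensities))
    stop("time_index must have one entry per row")
  dimnames(intensities) <- NULL
  structure(
    list(intensities = intensities, wavenumber = wavenumber,
         time_index = as.integer(time_index)),
    class = "spectra_matrix")
}

#' Construct a background-corrected spectra matrix
#'
#' Background-removed spectra are signed: after subtracting the projection on
#' the estimated background, noise fluctuates around zero and only analyte
#' bumps stand out as positive excursions.
#'
#' @param values numeric matrix of corrected intensities (signed), same shape
#'   as the source spectra.
#' @param wavenumber optional wavenumber axis (see [spectra_matrix()]).
#' @param params list recording the parameters used to produce the matrix
#'   (window sizes, percentile).
#' @return An object of class `corrected_spectra`.
#' @export
corrected_spectra <- function(values, wavenumber = NULL, params = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("values must have at least one row and one column")
  .check_finite(values, "values")
  wavenumber <- .check_wavenumber(wavenumber, ncol(values))
  dimnames(values) <- NULL
  structure(list(values = values, wavenumber = wavenumber, params = params),
            class = "corrected_spectra")
}

.check_finite <- function(x, what) {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value in %s at row %d, column %d",
                 what, bad[1, 1], bad[1, 2]))
  invisible(TRUE)
}

.check_wavenumber <- function(wavenumber, w) {
  if (is.null(wavenumber)) return(as.numeric(seq_len(w)))
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) != w)
    stop(sprintf("wavenumber has length %d; expected %d (one per channel)",
                 length(wavenumber), w))
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumber axis contains non-finite values")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber axis must be strictly increasing")
  wavenumber
}

#' @export
dim.spectra_matrix <- function(x) dim(x$intensities)

#' @export
dim.corrected_spectra <- function(x) dim(x$values)

#' @export
print.spectra_matrix <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<spectra_matrix> %d time points x %d frequency channels\n",
              d[1], d[2]))
  cat(sprintf("  wavenumber range: %.6g .. %.6g\n",
              x$wavenumber[1], x$wavenumber[d[2]]))
  invisible(x)
}

#' @export
print.corrected_spectra <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<corrected_spectra> %d time points x %d frequency channels\n",
              d[1], d[2]))
  if (length(x$params))
    cat("  parameters:", paste(names(x$params), unlist(x$params),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.delim_for <- function(path, dialect) {
  switch(dialect,
         tsv = "\t",
         csv = ",",
         auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
}

#' Read a spectra matrix from a delimited text file
#'
#' The on-disk format is a plain delimited matrix: an optional first row with
#' the wavenumber axis, then one spectrum per row, one frequency channel per
#' column.  Ragged rows, non-numeric cells, negative intensities and
#' non-monotone wavenumber headers are rejected with messages naming the
#' offending row and column.
#'
#' @param path path to a CSV or TSV file.
#' @param dialect `"auto"` (by file extension; default tab), `"tsv"` or
#'   `"csv"`.
#' @param header logical; if `TRUE` (default) the first row is the wavenumber
#'   axis.
#' @return A [spectra_matrix()].
#' @export
read_spectra <- function(path, dialect = c("auto", "tsv", "csv"),
                         header = TRUE) {
  dialect <- match.arg(dialect)
  x <- .read_matrix(path, .delim_for(path, dialect))
  if (header) {
    if (nrow(x) < 2L)
      stop("file has a header row but no spectra: ", path)
    spectra_matrix(x[-1L, , drop = FALSE], wavenumber = x[1L, ])
  } else {
    spectra_matrix(x)
  }
}

#' Read background-corrected spectra from a delimited text file
#'
#' Same format as [read_spectra()] but negative values are accepted, since
#' corrected spectra are signed.
#'
#' @inheritParams read_spectra
#' @return A [corrected_spectra()].
#' @export
read_corrected <- function(path, dialect = c("auto", "tsv", "csv"),
                           header = TRUE) {
  dialect <- match.arg(dialect)
  x <- .read_matrix(path, .delim_for(path, dialect))
  if (header) {
    if (nrow(x) < 2L)
      stop("file has a header row but no spectra: ", path)
    corrected_spectra(x[-1L, , drop = FALSE], wavenumber = x[1L, ])
  } else {
    corrected_spectra(x)
  }
}

.read_matrix <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  warned <- FALSE
  dt <- tryCatch(
    withCallingHandlers(
      data.table::fread(path, header = FALSE, sep = sep, data.table = FALSE,
                        colClasses = "numeric", fill = TRUE,
                        showProgress = FALSE),
      # let fread finish (aborting mid-call leaves its parser dirty) and
      # fall through to the diagnostic reader for a precise message
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(dt) || warned || anyNA(dt) ||
      !all(vapply(dt, is.numeric, logical(1))))
    .diagnose_matrix_file(path, sep)
  if (nrow(dt) < 1L) stop("empty file: ", path)
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  m
}

# Slow path, only entered on malformed input: pinpoint the bad row/cell.
.diagnose_matrix_file <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 bad, path, widths[bad], widths[1L]))
  }
  for (i in seq_along(cells)) {
    vals <- suppressWarnings(as.numeric(cells[[i]]))
    j <- which(is.na(vals))
    if (length(j) > 0)
      stop(sprintf("malformed numeric value %s at row %d, column %d of %s",
                   dQuote(trimws(cells[[i]][j[1L]])), i, j[1L], path))
  }
  stop("could not parse ", path, " as a numeric matrix")
}

#' Write a spectra matrix to a delimited text file
#'
#' Writes the wavenumber axis as the first row, then one spectrum per row.
#' Values are written with enough significant digits (15) that
#' [read_spectra()] / [read_corrected()] round-trip them to better than 1e-9
#' relative error.
#'
#' @param m a [spectra_matrix()] or [corrected_spectra()].
#' @param path output path; parent directory must exist and be writable.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(m, path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  vals <- if (inherits(m, "spectra_matrix")) m$intensities
          else if (inherits(m, "corrected_spectra")) m$values
          else as.matrix(m)
  wn <- if (is.list(m) && !is.null(m$wavenumber)) m$wavenumber
        else as.numeric(seq_len(ncol(vals)))
  out <- rbind(wn, vals)
  dimnames(out) <- NULL
  ok <- tryCatch({
    data.table::fwrite(as.data.frame(out), path,
                       sep = .delim_for(path, dialect),
                       col.names = FALSE, showProgress = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}
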
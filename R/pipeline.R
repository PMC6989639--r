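#' Assemble a pipeline configuration
#'
#' Collects all stage parameters for [run_pipeline()].  Two presets encode
#' common parameterisations: `"short-signal"` (window sizes 50/50, for
#' analyte signals lasting a few time points) and `"long-signal"` (time
#' window 150, for signals persisting over many time points, where a small
#' time window would eat into the signal).  Explicit arguments override the
#' preset.
#'
#' @param inputs character vector of spectra file paths, or a (named) list
#'   of [spectra_matrix()] objects; one entry per replicate.
#' @param output_dir directory for all tables and the run report; created
#'   if missing.
#' @param preset `"short-signal"`, `"long-signal"` or `NULL`.
#' @param w_time,w_freq,q background-removal parameters
#'   (see [remove_background()]).
#' @param alpha,beta,gamma detection cutoffs (see [detect_signals()]).
#' @param phi merge similarity threshold (see [merge_signals()]).
#' @param max_shift,min_similarity cross-experiment matching parameters
#'   (see [match_signatures()]).
#' @param verbose log each stage and its parameters via [message()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, output_dir,
                            preset = NULL,
                            w_time = NULL, w_freq = NULL, q = 40,
                            alpha = 3, beta = 0.05, gamma = 3,
                            phi = 0.9, max_shift = 10, min_similarity = 0.5,
                            verbose = TRUE) {
  defaults <- switch(
    if (is.null(preset)) "none" else preset,
    "short-signal" = list(w_time = 50, w_freq = 50),
    "long-signal" = list(w_time = 150, w_freq = 50),
    "none" = list(w_time = 50, w_freq = 50),
    stop("unknown preset: ", preset))
  if (is.null(w_time)) w_time <- defaults$w_time
  if (is.null(w_freq)) w_freq <- defaults$w_freq
  stopifnot(q > 0, q < 100, alpha > 0, beta > 0, beta < 1, gamma >= 1,
            phi > -1, phi < 1, max_shift >= 0, min_similarity <= 1)
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (length(inputs) == 0L) stop("at least one input replicate is required")
  nm <- names(inputs)
  if (is.null(nm) || any(!nzchar(nm)))
    names(inputs) <- sprintf("rep%d", seq_along(inputs))
  structure(
    list(inputs = inputs, output_dir = output_dir, preset = preset,
         w_time = w_time, w_freq = w_freq, q = q,
         alpha = alpha, beta = beta, gamma = gamma, phi = phi,
         max_shift = max_shift, min_similarity = min_similarity,
         verbose = verbose),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `inputs` is a
#' list of spectra file paths, resolved relative to the YAML file's
#' directory when not absolute.
#'
#' @param path path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  if (!is.null(y$inputs)) {
    base <- dirname(normalizePath(path))
    y$inputs <- lapply(y$inputs, function(p)
      if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p))
    y$inputs <- as.list(unlist(y$inputs))
  }
  do.call(pipeline_config, y)
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' For every replicate: background removal, signal detection, and merging
#' of consecutive detections into signature signals, writing the corrected
#' matrix, the detections table and the signatures (table plus spectra
#' matrix) to the output directory.  Afterwards, every pair of replicates
#' with at least one signature each is matched with the shift-tolerant
#' similarity metric.  The method itself has no stochastic step, so
#' re-running with identical inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return The run report, invisibly: a list with `parameters`,
#'   `replicates` (per replicate: dimensions, detected times, signature
#'   table) and `matches` (per pair).  Also written to
#'   `<output_dir>/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config or a YAML path")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  v <- config$verbose

  reps <- list()
  signatures <- list()
  for (nm in names(config$inputs)) {
    input <- config$inputs[[nm]]
    m <- tryCatch({
      if (is.character(input)) read_spectra(input) else input
    }, error = function(e)
      stop(sprintf("stage load, replicate %s: %s", nm,
                   conditionMessage(e)), call. = FALSE))
    if (!inherits(m, "spectra_matrix"))
      stop(sprintf("replicate %s is not a spectra_matrix", nm))
    .log_stage(v, "[%s] background removal (w_time=%d, w_freq=%d, q=%g)",
               nm, config$w_time, config$w_freq, config$q)
    cs <- tryCatch(
      remove_background(m, config$w_time, config$w_freq, config$q),
      error = function(e)
        stop(sprintf("stage background-removal, replicate %s: %s", nm,
                     conditionMessage(e)), call. = FALSE))
    write_spectra(cs, file.path(config$output_dir,
                                sprintf("corrected_%s.tsv", nm)))

    .log_stage(v, "[%s] signal detection (alpha=%g, beta=%g, gamma=%d)",
               nm, config$alpha, config$beta, config$gamma)
    det <- detect_signals(cs, config$alpha, config$beta, config$gamma)
    write_detections(det, file.path(config$output_dir,
                                    sprintf("detections_%s.tsv", nm)))

    .log_stage(v, "[%s] merging %d detection(s) (phi=%g)",
               nm, length(det$detected_times), config$phi)
    sigs <- merge_signals(cs, det, config$phi)
    write_signatures(sigs, file.path(config$output_dir,
                                     sprintf("signatures_%s.tsv", nm)))
    if (length(sigs) == 0L)
      .log_stage(v, "[%s] zero signatures; replicate excluded from matching",
                 nm)
    signatures[[nm]] <- sigs
    reps[[nm]] <- list(
      n_time = nrow(m$intensities), n_freq = ncol(m$intensities),
      detected_times = det$detected_times,
      signature_times = vapply(sigs, `[[`, integer(1), "time_index"),
      signatures = as.data.frame(sigs))
  }

  matches <- list()
  nms <- names(signatures)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        a <- nms[i]; b <- nms[j]
        if (length(signatures[[a]]) == 0L || length(signatures[[b]]) == 0L)
          next
        .log_stage(v, "matching %s vs %s (max_shift=%d, min_similarity=%g)",
                   a, b, config$max_shift, config$min_similarity)
        mt <- match_signatures(signatures[[a]], signatures[[b]],
                               config$max_shift, config$min_similarity)
        data.table::fwrite(
          mt, file.path(config$output_dir,
                        sprintf("matches_%s_%s.tsv", a, b)), sep = "\t")
        matches[[paste(a, b, sep = "_vs_")]] <- mt
      }
    }
  }

  report <- list(
    parameters = config[c("w_time", "w_freq", "q", "alpha", "beta", "gamma",
                          "phi", "max_shift", "min_similarity")],
    replicates = reps,
    matches = matches)
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Write / read a detections table
#'
#' TSV with columns `time_index`, `bump_start`, `bump_end`, `bump_length`,
#' `peak_value`, `min_fdr` (1-based closed channel intervals).  The reader
#' returns a minimal `detection_result` (detected times and bump supports)
#' sufficient for [merge_signals()].
#'
#' @param det a [detect_signals()] result.
#' @param path TSV path.
#' @return `write_detections()`: `path`, invisibly.  `read_detections()`:
#'   a `detection_result`.
#' @export
write_detections <- function(det, path) {
  data.table::fwrite(det$bumps, path, sep = "\t")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  b <- data.table::fread(path, sep = "\t", data.table = FALSE)
  structure(
    list(detected_times = sort(unique(as.integer(b$time_index))),
         bumps = b, noise_sd = NULL, pvalues = NULL, fdr_values = NULL,
         degenerate_rows = integer(0), params = list()),
    class = "detection_result")
}

#' Write / read signature signals
#'
#' The table (TSV) has columns `signature_index`, `time_index`, `support`
#' (intervals as `start-end` joined by `;`) and `strength`; the retained
#' spectra are stored alongside in `<path>` with suffix `_spectra`, one row
#' per signature, readable as a corrected matrix.
#'
#' @param sigs a `signature_list` from [merge_signals()].
#' @param path TSV path for the table; the spectra matrix goes to the same
#'   path with `_spectra` inserted before the extension.
#' @param wavenumber optional wavenumber axis for the spectra file.
#' @return `write_signatures()`: `path`, invisibly.  `read_signatures()`:
#'   a `signature_list`.
#' @export
write_signatures <- function(sigs, path, wavenumber = NULL) {
  tab <- as.data.frame(sigs)
  tab <- cbind(signature_index = seq_len(nrow(tab)), tab)
  data.table::fwrite(tab, path, sep = "\t")
  spath <- .spectra_sidecar(path)
  if (length(sigs) > 0L) {
    mat <- do.call(rbind, lapply(sigs, `[[`, "spectrum"))
    write_spectra(corrected_spectra(mat, wavenumber = wavenumber), spath)
  } else {
    unlink(spath)
  }
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (nrow(tab) == 0L) return(structure(list(), class = "signature_list"))
  mat <- read_corrected(.spectra_sidecar(path))$values
  if (nrow(mat) != nrow(tab))
    stop("signature table and spectra matrix disagree on the number of signatures")
  out <- lapply(seq_len(nrow(tab)), function(i)
    signature_signal(tab$time_index[i], mat[i, ],
                     .parse_intervals(tab$support[i]),
                     strength = tab$strength[i]))
  structure(out, class = "signature_list")
}

.spectra_sidecar <- function(path) {
  sub("(\\.[A-Za-z0-9]+)$", "_spectra\\1", path)
}
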
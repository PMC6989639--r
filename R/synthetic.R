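# Seeded generator of SERS-like spectra with known ground truth: a strong
# multiplicative background whose shape drifts slowly in time and whose
# per-spectrum strength varies arbitrarily, transient analyte signals that
# intensify and fade over a few consecutive time points, additive Gaussian
# noise, and occasional single-channel cosmic-ray spikes.

#' Default transient analyte signals for the simulator
#'
#' Three analyte events spread over the run, each lasting three consecutive
#' time points with a triangular intensify-then-fade intensity profile and a
#' spectral shape made of a few sharp Gaussian peaks.  Peak widths (3-5
#' channels) and spacings (several tens of channels) follow the sparse-band
#' structure of Raman fingerprints; sparsity matters to the background
#' estimator, which assumes signals occupy a minority of the channels in
#' any frequency window.
#'
#' @param n_time,n_freq dimensions of the target matrix.
#' @param amplitude peak amplitude in noise-SD units (default 6).
#' @return A list of signal descriptors (lists with `onset`, `duration`,
#'   `centers`, `widths`, `amplitude`).
#' @export
default_signals <- function(n_time, n_freq, amplitude = 6) {
  stopifnot(n_time >= 20, n_freq >= 60)
  at <- function(f) max(1L, min(n_time, as.integer(round(f * n_time))))
  ch <- function(f) max(1L, min(n_freq, as.integer(round(f * n_freq))))
  list(
    list(onset = at(0.25), duration = 3L,
         centers = c(ch(0.22), ch(0.32)), widths = c(4, 4),
         amplitude = amplitude),
    list(onset = at(0.50), duration = 3L,
         centers = c(ch(0.47), ch(0.57), ch(0.66)), widths = c(4, 3, 4),
         amplitude = amplitude),
    list(onset = at(0.75), duration = 3L,
         centers = c(ch(0.78), ch(0.90)), widths = c(4, 5),
         amplitude = amplitude))
}

#' Configuration for the SERS spectra simulator
#'
#' The generated matrix is
#' `X[t, j] = c_t * B_t(j) + sum_s a_s(t) g_s(j) + eps[t, j]`, clipped at 0:
#' a multiplicative background with per-time strength `c_t` (log-normal)
#' and a shape `B_t` drifting linearly between two fixed smooth profiles;
#' transient signals with triangular rise-fall time profiles `a_s` and
#' Gaussian-peak spectral shapes `g_s`; i.i.d. Gaussian noise `eps`; plus
#' Poisson-many single-channel cosmic-ray spikes.
#'
#' The default drift multiplies the low-frequency end of the background
#' down and the high-frequency end up over the run, emulating the slow,
#' region-specific shape change seen in real SERS time series; `drift_speed`
#' scales how much of that change happens within the run (0 freezes the
#' shape).
#'
#' @param n_time,n_freq matrix dimensions (default 600 x 400).
#' @param signals list of signal descriptors as in [default_signals()]; use
#'   `list()` for a signal-free matrix.
#' @param noise_sd additive noise SD in intensity units (default 1; 0
#'   gives a noiseless matrix for exactness checks).
#' @param background_level mean background intensity in noise-SD units
#'   (default 80): SERS backgrounds dwarf both noise and analyte signals.
#' @param drift relative amplitude of the background shape change between
#'   the start and end profiles (default 0.15).
#' @param drift_speed fraction of the full drift traversed during the run
#'   (default 1; 0 = constant shape).
#' @param strength_sdlog SD of the log of the per-time strength multiplier
#'   (default 0.4).
#' @param cosmic_ray_rate expected number of single-channel spikes per
#'   matrix (default 2).
#' @param seed integer seed; identical configurations generate
#'   bit-identical matrices.
#' @param background_shapes optional list of two strictly positive
#'   length-`n_freq` profiles overriding the built-in start/end shapes.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_time = 600, n_freq = 400,
                              signals = default_signals(n_time, n_freq),
                              noise_sd = 1, background_level = 80,
                              drift = 0.15, drift_speed = 1,
                              strength_sdlog = 0.4, cosmic_ray_rate = 2,
                              seed = 1, background_shapes = NULL) {
  cfg <- list(n_time = as.integer(n_time), n_freq = as.integer(n_freq),
              signals = signals, noise_sd = noise_sd,
              background_level = background_level, drift = drift,
              drift_speed = drift_speed, strength_sdlog = strength_sdlog,
              cosmic_ray_rate = cosmic_ray_rate, seed = as.integer(seed),
              background_shapes = background_shapes)
  .validate_sim_config(cfg)
  if (is.null(cfg$background_shapes))
    cfg$background_shapes <- .default_background_shapes(cfg)
  structure(cfg, class = "simulation_config")
}

.validate_sim_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$n_time >= 1 && cfg$n_freq >= 1, "n_time and n_freq must be >= 1")
  chk(is.numeric(cfg$noise_sd) && cfg$noise_sd >= 0,
      "noise_sd must be >= 0")
  chk(cfg$background_level > 0, "background_level must be > 0")
  chk(cfg$drift >= 0 && cfg$drift < 1, "drift must lie in [0, 1)")
  chk(cfg$drift_speed >= 0, "drift_speed must be >= 0")
  chk(cfg$strength_sdlog >= 0, "strength_sdlog must be >= 0")
  chk(cfg$cosmic_ray_rate >= 0, "cosmic_ray_rate must be >= 0")
  for (k in seq_along(cfg$signals)) {
    s <- cfg$signals[[k]]
    chk(all(c("onset", "duration", "centers", "widths", "amplitude") %in%
              names(s)), sprintf("signal %d is missing fields", k))
    if (!is.null(s$duration)) chk(s$duration >= 1,
                                  sprintf("signal %d: duration < 1", k))
    if (!is.null(s$amplitude)) chk(s$amplitude >= 0,
                                   sprintf("signal %d: amplitude < 0", k))
    if (!is.null(s$onset))
      chk(s$onset >= 1 && s$onset + s$duration - 1 <= cfg$n_time,
          sprintf("signal %d: time window outside 1..n_time", k))
    if (!is.null(s$widths)) chk(all(s$widths > 0),
                                sprintf("signal %d: widths must be > 0", k))
  }
  if (!is.null(cfg$background_shapes)) {
    chk(length(cfg$background_shapes) == 2L,
        "background_shapes must hold two profiles")
    for (sh in cfg$background_shapes)
      chk(length(sh) == cfg$n_freq && all(sh > 0),
          "each background shape must be strictly positive, length n_freq")
  }
  if (length(problems) > 0)
    stop("invalid simulation config:\n  ", paste(problems, collapse = "\n  "))
  invisible(TRUE)
}

# Deterministic smooth positive start/end shapes: broad overlapping peaks on
# a sloped base, with a drift factor that lowers the low-frequency end and
# raises the high-frequency end of the end shape relative to the start.
.default_background_shapes <- function(cfg) {
  w <- cfg$n_freq
  j <- seq_len(w) / w
  base <- 1 +
    0.8 * exp(-(j - 0.15)^2 / (2 * 0.08^2)) +
    0.5 * exp(-(j - 0.45)^2 / (2 * 0.15^2)) +
    0.7 * exp(-(j - 0.8)^2 / (2 * 0.1^2)) +
    0.3 * sin(2 * pi * j) + 0.4 * (1 - j)
  base <- base / mean(base) * cfg$background_level
  ramp <- seq(-1, 1, length.out = w)          # low end down, high end up
  shape2 <- base * (1 + cfg$drift * ramp)
  list(base, shape2)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic SERS spectra matrix with ground truth
#'
#' See [simulation_config()] for the generative model.  The returned ground
#' truth records, per signal, the time window, the channel support (where
#' the spectral shape exceeds 5% of its maximum), and the noiseless shape;
#' plus the full noiseless background matrix, the cosmic-ray positions and
#' the configuration itself.
#'
#' @param cfg a [simulation_config()].
#' @return A list with elements `spectra` (a [spectra_matrix()]) and
#'   `truth` (class `ground_truth`: `signal_times`, `signal_support`,
#'   `signal_shape`, `background_truth`, `cosmic_rays`, `config`).
#' @export
#' @examples
#' sim <- simulate_spectra(simulation_config(n_time = 120, n_freq = 100,
#'                                           seed = 7, signals = list()))
#' dim(sim$spectra)
simulate_spectra <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop("cfg must be a simulation_config")
  .with_seed(cfg$seed, {
    tt <- cfg$n_time; w <- cfg$n_freq
    lambda <- if (tt == 1L) 0 else
      pmin(1, cfg$drift_speed * (seq_len(tt) - 1) / (tt - 1))
    s1 <- cfg$background_shapes[[1L]]
    s2 <- cfg$background_shapes[[2L]]
    strength <- stats::rlnorm(tt, meanlog = 0, sdlog = cfg$strength_sdlog)
    bg <- (strength * (1 - lambda)) %o% s1 + (strength * lambda) %o% s2

    sig <- matrix(0, tt, w)
    signal_times <- vector("list", length(cfg$signals))
    signal_support <- vector("list", length(cfg$signals))
    signal_shape <- vector("list", length(cfg$signals))
    for (k in seq_along(cfg$signals)) {
      s <- cfg$signals[[k]]
      g <- rep(0, w)
      jj <- seq_len(w)
      for (p in seq_along(s$centers))
        g <- g + exp(-(jj - s$centers[p])^2 / (2 * s$widths[p]^2))
      g <- g / max(g)
      times <- s$onset:(s$onset + s$duration - 1L)
      mid <- (s$duration + 1) / 2
      prof <- 1 - abs(seq_len(s$duration) - mid) / mid   # rise then fade
      sig[times, ] <- sig[times, , drop = FALSE] +
        (s$amplitude * cfg$noise_sd * prof) %o% g
      signal_times[[k]] <- as.integer(times)
      signal_support[[k]] <- .coalesce_intervals(.channels_to_intervals(
        which(g > 0.05)))
      signal_shape[[k]] <- g
    }

    eps <- matrix(stats::rnorm(tt * w, sd = cfg$noise_sd), tt, w)
    n_rays <- stats::rpois(1L, cfg$cosmic_ray_rate)
    rays <- NULL
    if (n_rays > 0) {
      rays <- data.frame(
        time_index = sample.int(tt, n_rays, replace = TRUE),
        channel = sample.int(w, n_rays, replace = TRUE),
        magnitude = stats::runif(n_rays, 20, 50) * cfg$noise_sd)
      for (r in seq_len(n_rays))
        eps[rays$time_index[r], rays$channel[r]] <-
          eps[rays$time_index[r], rays$channel[r]] + rays$magnitude[r]
    } else {
      rays <- data.frame(time_index = integer(0), channel = integer(0),
                         magnitude = numeric(0))
    }

    x <- pmax(bg + sig + eps, 0)
    truth <- structure(
      list(signal_times = signal_times, signal_support = signal_support,
           signal_shape = signal_shape, background_truth = bg,
           strength = strength, cosmic_rays = rays, config = cfg),
      class = "ground_truth")
    list(spectra = spectra_matrix(x), truth = truth)
  })
}

.channels_to_intervals <- function(ch) {
  if (length(ch) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  ch <- sort(unique(as.integer(ch)))
  brk <- c(0L, which(diff(ch) > 1L), length(ch))
  data.frame(start = ch[brk[-length(brk)] + 1L], end = ch[brk[-1L]])
}

# Translate a profile by `s` channels, extending the edge value.
.shift_profile <- function(x, s) {
  w <- length(x)
  idx <- pmin(pmax(seq_len(w) - s, 1L), w)
  x[idx]
}

#' Generate a frequency-shifted replicate of a synthetic dataset
#'
#' Emulates a technical replicate recorded with a small wavenumber
#' miscalibration: the background shapes and the signal peak centers are
#' translated by `shift` channels (edge channels extend the boundary
#' value), and fresh noise, per-time strengths and cosmic rays are drawn
#' under the new seed.  Ground-truth supports translate accordingly.
#'
#' @param sim a `list(spectra, truth)` as returned by [simulate_spectra()].
#' @param shift signed channel offset; `|shift|` must be below a quarter of
#'   the channel count.
#' @param seed seed for the replicate's noise and strengths.
#' @return A `list(spectra, truth)` for the shifted replicate.
#' @export
shifted_replicate <- function(sim, shift, seed) {
  cfg <- sim$truth$config
  shift <- as.integer(shift)
  if (abs(shift) >= cfg$n_freq / 4)
    stop("|shift| must be below n_freq / 4")
  cfg2 <- unclass(cfg)
  cfg2$seed <- as.integer(seed)
  cfg2$background_shapes <- lapply(cfg$background_shapes, .shift_profile,
                                   s = shift)
  cfg2$signals <- lapply(cfg$signals, function(s) {
    s$centers <- pmin(pmax(s$centers + shift, 1L), cfg$n_freq)
    s
  })
  simulate_spectra(do.call(simulation_config, cfg2))
}
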
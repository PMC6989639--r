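# Fixture builders shared across test files.

# A minimal detection_result for driving merge_signals directly: one bump
# support per detected time.
make_detection <- function(times, supports) {
  bumps <- do.call(rbind, lapply(seq_along(times), function(k) {
    iv <- supports[[k]]
    data.frame(time_index = times[k], bump_start = iv$start,
               bump_end = iv$end,
               bump_length = iv$end - iv$start + 1L,
               peak_value = NA_real_, min_fdr = NA_real_)
  }))
  structure(list(detected_times = as.integer(times), bumps = bumps,
                 params = list()),
            class = "detection_result")
}

iv <- function(start, end) data.frame(start = as.integer(start),
                                      end = as.integer(end))

# Translate a vector by d channels (positive d moves it toward higher
# indices), filling vacated channels with 0.
translate_vec <- function(x, d) {
  w <- length(x)
  out <- rep(0, w)
  src <- seq_len(w) - d
  ok <- src >= 1 & src <= w
  out[ok] <- x[src[ok]]
  out
}

shift_df <- function(sup, d) data.frame(start = sup$start + d,
                                        end = sup$end + d)

# A signature signal with a single Gaussian peak, zero elsewhere.
peak_signature <- function(w, center, width = 4, amplitude = 10,
                           time_index = 1L, noise = NULL) {
  spec <- amplitude * exp(-(seq_len(w) - center)^2 / (2 * width^2))
  if (!is.null(noise)) spec <- spec + noise
  half <- ceiling(2.5 * width)
  signature_signal(time_index, spec,
                   iv(max(1, center - half), min(w, center + half)))
}

# Pure multiplicative background with a per-block constant shape and
# arbitrary per-time strengths; exactly annihilated by remove_background
# when windows align with the block grid.
blockwise_background <- function(n_t, n_f, w_time, w_freq) {
  x <- matrix(0, n_t, n_f)
  g <- partition_blocks(n_t, n_f, w_time, w_freq)
  strength <- exp(rnorm(n_t, sd = 0.8))
  b <- g$blocks
  for (k in seq_len(nrow(b))) {
    ti <- b$t_start[k]:b$t_end[k]
    fi <- b$f_start[k]:b$f_end[k]
    shape <- exp(rnorm(length(fi), sd = 0.5)) + 0.2
    x[ti, fi] <- strength[ti] %o% shape
  }
  x
}
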
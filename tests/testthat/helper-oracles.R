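# Independent literal-definition oracles. These deliberately use plain
# loops and no code path shared with the package implementation.

# Background removal, written as the per-definition triple loop: segment
# both axes (floor count, remainder absorbed into the final segment), scale
# each fragment row by its mean, per-channel median shape, per-row q-th
# percentile of the pointwise projection, subtract.
naive_remove_background <- function(x, w_time, w_freq, q = 40) {
  n_t <- nrow(x); n_f <- ncol(x)
  seg <- function(n, w) {
    k <- floor(n / w)
    lapply(seq_len(k), function(i) {
      lo <- (i - 1) * w + 1
      hi <- if (i == k) n else i * w
      lo:hi
    })
  }
  y <- matrix(NA_real_, n_t, n_f)
  for (ts in seg(n_t, w_time)) {
    for (fs in seg(n_f, w_freq)) {
      frag <- x[ts, fs, drop = FALSE]
      scaled <- frag
      for (i in seq_len(nrow(frag)))
        scaled[i, ] <- frag[i, ] / mean(frag[i, ])
      b <- numeric(ncol(frag))
      for (j in seq_len(ncol(frag)))
        b[j] <- median(scaled[, j])
      for (i in seq_len(nrow(frag))) {
        p <- frag[i, ] / b
        qi <- quantile(p, probs = q / 100, type = 7, names = FALSE)
        y[ts[i], fs] <- frag[i, ] - qi * b
      }
    }
  }
  y
}

# Benjamini-Hochberg step-up, literally: sort, multiply by m/rank, running
# minimum from the largest rank down, clip at 1, restore input order.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
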
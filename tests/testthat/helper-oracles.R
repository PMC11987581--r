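# Independent brute-force oracles used across the suite. These deliberately
# avoid FFTs and library convolutions so they can certify the fast paths.

# direct-sum cyclic spatiotemporal correlation of one stack; means are the
# per-frame spatial means of the intensity stack used for normalization
oracle_correlation <- function(stack, tau, means, lags_row, lags_col) {
  d <- dim(stack)
  np <- d[1] * d[2]
  acc <- matrix(0, d[1], d[2])
  for (t in seq_len(d[3] - tau)) {
    cc <- matrix(0, d[1], d[2])
    for (ei in seq_len(d[1])) for (xj in seq_len(d[2])) {
      eta <- lags_row[ei]; xi <- lags_col[xj]
      s <- 0
      for (x in seq_len(d[1])) for (y in seq_len(d[2]))
        s <- s + stack[x, y, t] * stack[(x - 1 + eta) %% d[1] + 1,
                                        (y - 1 + xi) %% d[2] + 1, t + tau]
      cc[ei, xj] <- s / (np * means[t] * means[t + tau])
    }
    acc <- acc + cc
  }
  acc / (d[3] - tau)
}

# direct windowed-sum local mean with replicate edge extension
oracle_local_mean <- function(frame, weights) {
  d <- dim(frame)
  side <- dim(weights)[1]
  r <- (side - 1L) %/% 2L
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- min(max(i + a, 1L), d[1])
      jj <- min(max(j + b, 1L), d[2])
      s <- s + frame[ii, jj] * weights[a + r + 1L, b + r + 1L]
    }
    out[i, j] <- s
  }
  out
}

# a small series of Gaussian spots on a quiet background, useful wherever a
# structured nonnegative test image is needed
spot_series <- function(n = 32, centers, sigma = 2, n_frames = 1,
                        shift_per_frame = c(0, 0), background = 0.1) {
  fr <- array(background, c(n, n, n_frames))
  for (t in seq_len(n_frames)) {
    for (k in seq_len(nrow(centers))) {
      cy <- centers[k, 1] + (t - 1) * shift_per_frame[1]
      cx <- centers[k, 2] + (t - 1) * shift_per_frame[2]
      fr[, , t] <- fr[, , t] + outer(
        exp(-(seq_len(n) - cy)^2 / (2 * sigma^2)),
        exp(-(seq_len(n) - cx)^2 / (2 * sigma^2)))
    }
  }
  fr
}
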
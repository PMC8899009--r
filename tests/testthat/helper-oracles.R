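# Explicit-loop reimplementations used as independent oracles. These are
# deliberately naive (elementwise loops) and never share code with the
# package internals they check.

loop_squeeze <- function(f) {
  # f: (C, H, W)
  d <- dim(f)
  z <- numeric(d[1])
  for (c in seq_len(d[1])) {
    acc <- 0
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) acc <- acc + f[c, i, j]
    z[c] <- acc / (d[2] * d[3])
  }
  z
}

loop_excite <- function(z, W1, W2) {
  hid <- nrow(W1)
  h <- numeric(hid)
  for (r in seq_len(hid)) {
    acc <- 0
    for (c in seq_along(z)) acc <- acc + W1[r, c] * z[c]
    h[r] <- max(acc, 0)
  }
  s <- numeric(nrow(W2))
  for (r in seq_len(nrow(W2))) {
    acc <- 0
    for (c in seq_len(hid)) acc <- acc + W2[r, c] * h[c]
    s[r] <- 1 / (1 + exp(-acc))
  }
  s
}

loop_channel_scale <- function(f, s) {
  d <- dim(f)
  out <- array(0, d)
  for (c in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    out[c, i, j] <- s[c] * f[c, i, j]
  out
}

loop_pool_maps <- function(f) {
  # f: (C, H, W) -> list(avg (H, W), max (H, W))
  d <- dim(f)
  avg <- matrix(0, d[2], d[3])
  mx <- matrix(-Inf, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    acc <- 0
    for (c in seq_len(d[1])) {
      acc <- acc + f[c, i, j]
      if (f[c, i, j] > mx[i, j]) mx[i, j] <- f[c, i, j]
    }
    avg[i, j] <- acc / d[1]
  }
  list(avg = avg, max = mx)
}

loop_conv2d_same <- function(x, W, b) {
  # x: (H, W, Cin); W: (k, k, Cin, 1); same padding, stride 1
  d <- dim(x)
  k <- dim(W)[1]
  p <- (k - 1) %/% 2
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- b
    for (ki in seq_len(k)) for (kj in seq_len(k)) for (c in seq_len(d[3])) {
      ii <- i + ki - 1 - p
      jj <- j + kj - 1 - p
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        acc <- acc + W[ki, kj, c, 1] * x[ii, jj, c]
    }
    out[i, j] <- acc
  }
  out
}

loop_rotate90cw <- function(img) {
  # out[i, j] = in[H - j + 1, i]
  d <- dim(img)
  out <- array(0L, c(d[2], d[1], d[3]))
  for (i in seq_len(d[2])) for (j in seq_len(d[1])) for (ch in seq_len(d[3]))
    out[i, j, ch] <- img[d[1] - j + 1, i, ch]
  out
}

rand_cwh <- function(C, H, W, seed) {
  set.seed(seed)
  array(stats::rnorm(C * H * W), c(C, H, W))
}
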
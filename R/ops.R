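# Internal tensor layout: activations are numeric arrays with dim
# (H, W, C, N) -- spatial fastest, so im2col slices are contiguous.
# User-facing attention functions take the conventional (C, H, W) layout
# and convert (see pcsa.R).

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' He-uniform weight initialization
#'
#' Draws from U(-limit, limit) with limit = sqrt(6 / fan_in), the standard
#' initialization for ReLU networks.
#'
#' @param dims integer vector of array dimensions.
#' @param fan_in number of input units feeding each output unit.
#' @return numeric array of dimension `dims`.
#' @keywords internal
he_uniform <- function(dims, fan_in) {
  limit <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

pad_spatial <- function(x, pad, value = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# ---- convolution ------------------------------------------------------------

conv2d_init <- function(kh, kw, cin, cout, bias = FALSE) {
  list(W = he_uniform(c(kh, kw, cin, cout), fan_in = kh * kw * cin),
       b = if (bias) numeric(cout) else NULL)
}

# im2col: returns (Ho*Wo*N) x (kh*kw*Cin) matrix whose column order matches
# the column-major flattening of the (kh, kw, Cin, Cout) weight array.
im2col <- function(xp, kh, kw, stride, Ho, Wo) {
  d <- dim(xp)
  Cin <- d[3]; N <- d[4]
  A <- array(0, c(Ho * Wo * N, kh * kw * Cin))
  cidx0 <- (seq_len(Cin) - 1L) * (kh * kw)
  ri <- lapply(seq_len(kh), function(ki) seq(ki, by = stride, length.out = Ho))
  rj <- lapply(seq_len(kw), function(kj) seq(kj, by = stride, length.out = Wo))
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      patch <- xp[ri[[ki]], rj[[kj]], , , drop = FALSE]
      patch <- aperm(patch, c(1, 2, 4, 3))          # (Ho, Wo, N, Cin)
      dim(patch) <- c(Ho * Wo * N, Cin)
      A[, cidx0 + (kj - 1L) * kh + ki] <- patch
    }
  }
  A
}

conv2d_fwd <- function(x, par, stride = 1, pad = 0) {
  d <- dim(x)
  kd <- dim(par$W)
  kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  stopifnot(kd[3] == d[3])
  Ho <- (d[1] + 2 * pad - kh) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - kw) %/% stride + 1L
  if (Ho < 1 || Wo < 1) stop("conv2d: input too small for kernel/stride")
  xp <- pad_spatial(x, pad)
  A <- im2col(xp, kh, kw, stride, Ho, Wo)
  y <- A %*% matrix(par$W, ncol = Cout)
  if (!is.null(par$b)) y <- y + rep(par$b, each = nrow(y))
  out <- aperm(array(y, c(Ho, Wo, d[4], Cout)), c(1, 2, 4, 3))
  list(out = out,
       cache = list(A = A, xdim = d, kh = kh, kw = kw, stride = stride,
                    pad = pad, Ho = Ho, Wo = Wo, has_bias = !is.null(par$b)))
}

conv2d_bwd <- function(dout, cache, par) {
  kd <- dim(par$W)
  Cout <- kd[4]
  dmat <- aperm(dout, c(1, 2, 4, 3))
  dim(dmat) <- c(cache$Ho * cache$Wo * cache$xdim[4], Cout)
  dW <- crossprod(cache$A, dmat)
  dim(dW) <- kd
  db <- if (cache$has_bias) colSums(dmat) else NULL
  dA <- dmat %*% t(matrix(par$W, ncol = Cout))
  d <- cache$xdim
  Cin <- d[3]; N <- d[4]
  pad <- cache$pad
  dxp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, Cin, N))
  cidx0 <- (seq_len(Cin) - 1L) * (cache$kh * cache$kw)
  for (kj in seq_len(cache$kw)) {
    for (ki in seq_len(cache$kh)) {
      block <- dA[, cidx0 + (kj - 1L) * cache$kh + ki, drop = FALSE]
      block <- aperm(array(block, c(cache$Ho, cache$Wo, N, Cin)), c(1, 2, 4, 3))
      ri <- seq(ki, by = cache$stride, length.out = cache$Ho)
      rj <- seq(kj, by = cache$stride, length.out = cache$Wo)
      dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] + block
    }
  }
  dx <- if (pad > 0) dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization ----------------------------------------------------

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       rm = numeric(C), rv = rep(1, C))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Normalizes per channel over (H, W, N). Returns updated running stats when
# training (caller stores them back on the model).
bn_fwd <- function(x, par, training, momentum = BN_MOMENTUM) {
  d <- dim(x)
  C <- d[3]; M <- d[1] * d[2] * d[4]
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(M, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = M)
    v <- colMeans(xc * xc)
    rm <- (1 - momentum) * par$rm + momentum * mu
    rv <- (1 - momentum) * par$rv + momentum * v
  } else {
    mu <- par$rm; v <- par$rv
    xc <- xm - rep(mu, each = M)
    rm <- par$rm; rv <- par$rv
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(istd, each = M)
  ym <- xhat * rep(par$gamma, each = M) + rep(par$beta, each = M)
  y <- array(ym, c(d[1], d[2], d[4], C))
  y <- aperm(y, c(1, 2, 4, 3))
  list(out = y, rm = rm, rv = rv,
       cache = list(xhat = xhat, istd = istd, d = d, M = M, training = training))
}

bn_bwd <- function(dout, cache, par) {
  d <- cache$d; C <- d[3]; M <- cache$M
  dym <- aperm(dout, c(1, 2, 4, 3))
  dim(dym) <- c(M, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(par$gamma, each = M)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- (dxhat - rep(s1 / M, each = M) -
              cache$xhat * rep(s2 / M, each = M)) * rep(cache$istd, each = M)
  } else {
    dxm <- dxhat * rep(cache$istd, each = M)
  }
  dx <- array(dxm, c(d[1], d[2], d[4], C))
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- pooling ----------------------------------------------------------------

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  xp <- pad_spatial(x, pad, value = -Inf)
  best <- array(-Inf, c(Ho, Wo, d[3], d[4]))
  arg <- array(0L, c(Ho, Wo, d[3], d[4]))
  q <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      q <- q + 1L
      ri <- seq(ki, by = stride, length.out = Ho)
      rj <- seq(kj, by = stride, length.out = Wo)
      patch <- xp[ri, rj, , , drop = FALSE]
      sel <- patch > best
      best[sel] <- patch[sel]
      arg[sel] <- q
    }
  }
  list(out = best,
       cache = list(arg = arg, xdim = d, k = k, stride = stride, pad = pad,
                    Ho = Ho, Wo = Wo))
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$xdim
  pad <- cache$pad; k <- cache$k
  dxp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  q <- 0L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      q <- q + 1L
      ri <- seq(ki, by = cache$stride, length.out = cache$Ho)
      rj <- seq(kj, by = cache$stride, length.out = cache$Wo)
      contrib <- dout * (cache$arg == q)
      dxp[ri, rj, , ] <- dxp[ri, rj, , , drop = FALSE] + contrib
    }
  }
  if (pad > 0) dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE] else dxp
}

global_avgpool_fwd <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(m), d[3], d[4])     # (C, N)
  list(out = out, cache = d)
}

global_avgpool_bwd <- function(dout, xdim) {
  hw <- xdim[1] * xdim[2]
  array(rep(as.vector(dout) / hw, each = hw), dim = xdim)
}

# ---- dense + loss -----------------------------------------------------------

dense_init <- function(cin, cout) {
  list(W = he_uniform(c(cout, cin), fan_in = cin), b = numeric(cout))
}

dense_fwd <- function(a, par) {
  # a: (C, N) -> (K, N)
  list(out = par$W %*% a + par$b, cache = a)
}

dense_bwd <- function(dout, a, par) {
  list(dx = crossprod(par$W, dout),
       dW = tcrossprod(dout, a),
       db = rowSums(dout))
}

# Numerically stable softmax over columns of a (K, N) score matrix.
softmax_cols <- function(logits) {
  z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# labels are 0-based class indices; returns mean cross-entropy and dlogits.
softmax_xent <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  stopifnot(length(labels) == N, all(labels >= 0 & labels < K))
  p <- softmax_cols(logits)
  idx <- cbind(labels + 1L, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N)
}
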
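# Parallel channel-spatial attention (PCSA).
#
# The module applies two gating branches to the SAME input feature map F:
#   * channel branch (squeeze/excite/scale): global average pooling to a
#     per-channel descriptor z, a two-layer bottlenecked mapping
#     s = sigmoid(W2 relu(W1 z)) with reduction ratio r, and channelwise
#     rescaling Q = s * F;
#   * spatial branch: channelwise average- and max-pooling maps combined
#     elementwise, fused by a same-padding k x k convolution and gated by a
#     sigmoid, giving a weight map M in (0,1)^{HxW} and P = M * F.
# The branch outputs are fused elementwise: G = relu(Q * P).
#
# User-facing functions take feature maps in the conventional (C, H, W)
# layout; the batched (H, W, C, N) path used inside the backbone lives in
# attn_fwd()/attn_bwd() below.

#' Configuration for an attention module
#'
#' @param reduction_ratio positive integer `r`; the excitation hidden layer
#'   has `C / r` units, trading capacity against parameters. Must divide the
#'   channel count the module is built for. Default 16.
#' @param spatial_kernel odd positive integer side of the spatial fusion
#'   convolution (default 7); odd so that same-padding preserves H x W.
#' @param seed integer seed for weight initialization (required so built
#'   modules are reproducible).
#' @param spatial_combine how the channelwise average- and max-pooling maps
#'   are combined: `"product"` (elementwise product, the default) or
#'   `"concat"` (stacked as two channels, the CBAM dialect).
#' @param spatial_conv logical; apply the fusion convolution in the spatial
#'   branch (default TRUE). When FALSE the sigmoid is applied directly to the
#'   combined pooling map.
#' @param fc_bias logical; include bias terms in the two excitation layers
#'   (default FALSE, the squeeze-and-excitation convention).
#' @return an object of class `pcsa_config`.
#' @export
pcsa_config <- function(reduction_ratio = 16L, spatial_kernel = 7L, seed = 1L,
                        spatial_combine = c("product", "concat"),
                        spatial_conv = TRUE, fc_bias = FALSE) {
  spatial_combine <- match.arg(spatial_combine)
  reduction_ratio <- as.integer(reduction_ratio)
  spatial_kernel <- as.integer(spatial_kernel)
  if (reduction_ratio < 1) stop("reduction_ratio must be a positive integer")
  if (spatial_kernel < 1 || spatial_kernel %% 2L == 0L)
    stop("spatial_kernel must be an odd positive integer")
  structure(list(reduction_ratio = reduction_ratio,
                 spatial_kernel = spatial_kernel,
                 seed = as.integer(seed),
                 spatial_combine = spatial_combine,
                 spatial_conv = spatial_conv,
                 fc_bias = fc_bias),
            class = "pcsa_config")
}

#' Build (initialize) an attention module for a given channel count
#'
#' @param channels number of input channels C. Must be divisible by
#'   `config$reduction_ratio`.
#' @param config a [pcsa_config()].
#' @param variant `"pcsa"` (parallel fusion), `"se"` (channel branch only) or
#'   `"cbam"` (serial channel-then-spatial gating).
#' @return an object of class `pcsa_module` holding the learnable state.
#' @export
pcsa_init <- function(channels, config = pcsa_config(), variant = "pcsa") {
  C <- as.integer(channels)
  r <- config$reduction_ratio
  if (C < 1) stop("channels must be >= 1")
  if (C %% r != 0L)
    stop(sprintf("channels (%d) must be divisible by reduction_ratio (%d)", C, r))
  variant <- match.arg(variant, c("pcsa", "se", "cbam"))
  set.seed(config$seed)
  hid <- C %/% r
  params <- list(
    W1 = he_uniform(c(hid, C), fan_in = C),
    W2 = he_uniform(c(C, hid), fan_in = hid)
  )
  if (config$fc_bias) {
    params$b1 <- numeric(hid)
    params$b2 <- numeric(C)
  }
  if (variant != "se" && config$spatial_conv) {
    k <- config$spatial_kernel
    ncomb <- if (config$spatial_combine == "concat" || variant == "cbam") 2L else 1L
    params$conv <- conv2d_init(k, k, ncomb, 1L, bias = TRUE)
    # start the spatial gate mostly open (M ~ 0.73) so the fused module's
    # early contribution is not doubly attenuated
    params$conv$b[] <- 1
  }
  structure(list(channels = C, config = config, variant = variant,
                 params = params),
            class = "pcsa_module")
}

#' Number of learnable parameters in an attention module
#'
#' For the default configuration (no excitation biases, product combine,
#' fusion kernel k) the count is `2 C^2 / r` for the two excitation maps plus
#' `k^2 + 1` for the fusion convolution and its bias.
#'
#' @param module a `pcsa_module`.
#' @return integer parameter count.
#' @export
pcsa_param_count <- function(module) {
  length(unlist(module$params, use.names = FALSE))
}

check_cwh <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L)
    stop("feature map must be a 3-d array with dimensions (C, H, W)")
  if (any(dim(f) < 1L)) stop("feature map dimensions must all be >= 1")
  if (!all(is.finite(f))) stop("feature map must be finite")
  invisible(dim(f))
}

#' Squeeze: global average pooling to a per-channel descriptor
#'
#' `z[c] = mean over (i, j) of f[c, i, j]`.
#'
#' @param f numeric array (C, H, W).
#' @return numeric vector of length C.
#' @export
squeeze <- function(f) {
  d <- check_cwh(f)
  rowMeans(matrix(f, d[1], d[2] * d[3]))
}

#' Excite: two-layer gating from a channel descriptor
#'
#' Computes `sigmoid(W2 %*% relu(W1 %*% z))`: the descriptor is reduced to
#' C/r units (FC-1, ReLU) and restored to C gate weights (FC-2, sigmoid).
#'
#' @param z numeric vector of length C.
#' @param module a `pcsa_module` built for C channels.
#' @return numeric vector of C weights, each strictly in (0, 1).
#' @export
excite <- function(z, module) {
  p <- module$params
  if (length(z) != ncol(p$W1))
    stop(sprintf("descriptor length %d does not match module channels %d",
                 length(z), ncol(p$W1)))
  h <- p$W1 %*% z
  if (!is.null(p$b1)) h <- h + p$b1
  h <- relu(h)
  s <- p$W2 %*% h
  if (!is.null(p$b2)) s <- s + p$b2
  as.vector(sigmoid(s))
}

#' Scale a feature map channelwise
#'
#' `out[c, i, j] = s[c] * f[c, i, j]` -- the channel-branch output Q.
#'
#' @param f numeric array (C, H, W).
#' @param s numeric vector of length C.
#' @return array with the shape of `f`.
#' @export
channel_scale <- function(f, s) {
  d <- check_cwh(f)
  if (length(s) != d[1])
    stop(sprintf("weight length %d does not match channel count %d",
                 length(s), d[1]))
  f * as.vector(s)     # C is the fastest dimension, so recycling is per-channel
}

#' Spatial gate: cross-channel pooling, fusion convolution, sigmoid
#'
#' Computes the channelwise mean and max maps, combines them (product by
#' default), applies the same-padding fusion convolution when configured, and
#' gates with a sigmoid to produce `M` in `(0,1)^{1 x H x W}`; the gated map
#' is `P[c, i, j] = M[i, j] * f[c, i, j]`.
#'
#' @param f numeric array (C, H, W).
#' @param module a `pcsa_module`.
#' @return list with elements `M` (array 1 x H x W) and `P` (shape of `f`).
#' @export
spatial_gate <- function(f, module) {
  d <- check_cwh(f)
  x <- aperm(array(f, c(d[1], d[2], d[3], 1L)), c(2, 3, 1, 4))  # (H, W, C, 1)
  res <- spatial_branch_fwd(x, module$params, module$config)
  M <- array(res$M, c(1L, d[2], d[3]))
  P <- aperm(res$P, c(3, 1, 2, 4))
  dim(P) <- d
  list(M = M, P = P)
}

#' Full parallel attention forward pass
#'
#' Computes the channel-branch output Q and spatial-branch output P from the
#' same input, then fuses them: `G = relu(Q * P)` elementwise. G has the
#' input's shape and is non-negative.
#'
#' @param f numeric array (C, H, W).
#' @param module a `pcsa_module` built for `dim(f)[1]` channels.
#' @return numeric array, same shape as `f`.
#' @export
pcsa_forward <- function(f, module) {
  d <- check_cwh(f)
  if (d[1] != module$channels)
    stop(sprintf("feature map has %d channels but module was built for %d",
                 d[1], module$channels))
  x <- aperm(array(f, c(d[1], d[2], d[3], 1L)), c(2, 3, 1, 4))
  out <- attn_fwd(x, module$params, module$config, module$variant)$out
  g <- aperm(out, c(3, 1, 2, 4))
  dim(g) <- d
  g
}

# ---- batched internals ------------------------------------------------------

# x: (H, W, C, N). Returns z (C, N), s (C, N), pre-activation h cache.
channel_branch_fwd <- function(x, params) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- x
  dim(m) <- c(hw, d[3] * d[4])
  z <- matrix(colMeans(m), d[3], d[4])
  pre1 <- params$W1 %*% z
  if (!is.null(params$b1)) pre1 <- pre1 + params$b1
  h <- relu(pre1)
  pre2 <- params$W2 %*% h
  if (!is.null(params$b2)) pre2 <- pre2 + params$b2
  s <- sigmoid(pre2)
  list(z = z, pre1 = pre1, h = h, s = s)
}

# ds: (C, N) gradient wrt gate weights s. Returns dx contribution and grads.
channel_branch_bwd <- function(ds, cb, x, params) {
  d <- dim(x)
  hw <- d[1] * d[2]
  dpre2 <- ds * cb$s * (1 - cb$s)
  dW2 <- tcrossprod(dpre2, cb$h)
  db2 <- if (!is.null(params$b2)) rowSums(dpre2) else NULL
  dh <- crossprod(params$W2, dpre2)
  dpre1 <- dh * (cb$pre1 > 0)
  dW1 <- tcrossprod(dpre1, cb$z)
  db1 <- if (!is.null(params$b1)) rowSums(dpre1) else NULL
  dz <- crossprod(params$W1, dpre1)
  dx <- array(rep(as.vector(dz) / hw, each = hw), dim = d)
  list(dx = dx, dW1 = dW1, dW2 = dW2, db1 = db1, db2 = db2)
}

expand_channel_gate <- function(s, d) {
  # s: (C, N) -> (H, W, C, N)
  array(rep(as.vector(s), each = d[1] * d[2]), dim = d)
}

expand_spatial_gate <- function(M, d) {
  # M: (H, W, N) -> (H, W, C, N)
  aperm(array(as.vector(M), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# x: (H, W, C, N). Computes M (H, W, N) and P = M * x, with caches.
spatial_branch_fwd <- function(x, params, config,
                               combine = config$spatial_combine) {
  d <- dim(x)
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(d[1] * d[2] * d[4], d[3])
  favg <- rowMeans(xp)
  amax <- max.col(xp, ties.method = "first")
  fmax <- xp[cbind(seq_len(nrow(xp)), amax)]
  if (combine == "concat") {
    comb <- array(c(favg, fmax), c(d[1], d[2], d[4], 2L))
    comb <- aperm(comb, c(1, 2, 4, 3))                  # (H, W, 2, N)
  } else {
    comb <- array(favg * fmax, c(d[1], d[2], 1L, d[4]))
  }
  if (config$spatial_conv) {
    k <- config$spatial_kernel
    cv <- conv2d_fwd(comb, params$conv, stride = 1L, pad = (k - 1L) %/% 2L)
    logits <- cv$out
    conv_cache <- cv$cache
  } else {
    logits <- comb
    conv_cache <- NULL
  }
  M <- sigmoid(array(logits, c(d[1], d[2], d[4])))
  ME <- expand_spatial_gate(M, d)
  list(M = M, P = ME * x, ME = ME,
       cache = list(favg = favg, fmax = fmax, amax = amax,
                    conv_cache = conv_cache, d = d, combine = combine))
}

# dP: gradient wrt P = M * x; also accepts an extra gradient dM_extra wrt M.
spatial_branch_bwd <- function(dP, sb, x, params, config) {
  cc <- sb$cache
  d <- cc$d
  dx <- dP * sb$ME
  dMfull <- dP * x                                       # (H, W, C, N)
  dm <- aperm(dMfull, c(1, 2, 4, 3))
  dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  dM <- rowSums(dm)                                      # wrt M (H*W*N)
  Mv <- as.vector(sb$M)
  dlog <- dM * Mv * (1 - Mv)
  grads <- list()
  if (config$spatial_conv) {
    dlog_arr <- array(dlog, c(d[1], d[2], 1L, d[4]))
    cb <- conv2d_bwd(dlog_arr, cc$conv_cache, params$conv)
    grads$conv <- list(W = cb$dW, b = cb$db)
    dcomb <- cb$dx
  } else {
    dcomb <- array(dlog, c(d[1], d[2], 1L, d[4]))
  }
  n <- d[1] * d[2] * d[4]
  if (cc$combine == "concat") {
    dc <- aperm(dcomb, c(1, 2, 4, 3))                    # (H, W, N, 2)
    dim(dc) <- c(n, 2L)
    dfavg <- dc[, 1L]
    dfmax <- dc[, 2L]
  } else {
    dcv <- as.vector(dcomb)
    dfavg <- dcv * cc$fmax
    dfmax <- dcv * cc$favg
  }
  # mean over channels
  davg_full <- aperm(array(rep(dfavg / d[3], times = d[3]),
                           c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  # max over channels: route to argmax channel
  dmx <- matrix(0, n, d[3])
  dmx[cbind(seq_len(n), cc$amax)] <- dfmax
  dmax_full <- aperm(array(dmx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  dx <- dx + davg_full + dmax_full
  list(dx = dx, grads = grads)
}

# Full attention forward on batched input. variant: pcsa | se | cbam | none.
attn_fwd <- function(x, params, config, variant) {
  if (variant == "none") return(list(out = x, cache = list(variant = "none")))
  if (variant == "se") {
    cb <- channel_branch_fwd(x, params)
    sE <- expand_channel_gate(cb$s, dim(x))
    return(list(out = x * sE,
                cache = list(variant = "se", cb = cb, sE = sE, x = x)))
  }
  if (variant == "cbam") {
    cb <- channel_branch_fwd(x, params)
    sE <- expand_channel_gate(cb$s, dim(x))
    y1 <- x * sE
    sb <- spatial_branch_fwd(y1, params, config, combine = "concat")
    return(list(out = sb$P,
                cache = list(variant = "cbam", cb = cb, sE = sE, sb = sb,
                             x = x, y1 = y1)))
  }
  # parallel: both branches see the same input
  cb <- channel_branch_fwd(x, params)
  sE <- expand_channel_gate(cb$s, dim(x))
  Q <- x * sE
  sb <- spatial_branch_fwd(x, params, config)
  P <- sb$P
  QP <- Q * P
  G <- relu(QP)
  list(out = G,
       cache = list(variant = "pcsa", cb = cb, sE = sE, sb = sb,
                    Q = Q, P = P, QP = QP, x = x))
}

attn_bwd <- function(dout, cache, params, config) {
  v <- cache$variant
  if (v == "none") return(list(dx = dout, grads = list()))
  if (v == "se") {
    x <- cache$x
    dx <- dout * cache$sE
    ds_mat <- dout * x
    d <- dim(x); hw <- d[1] * d[2]
    dim(ds_mat) <- c(hw, d[3] * d[4])
    ds <- matrix(colSums(ds_mat), d[3], d[4])
    cbg <- channel_branch_bwd(ds, cache$cb, x, params)
    return(list(dx = dx + cbg$dx,
                grads = list(W1 = cbg$dW1, W2 = cbg$dW2,
                             b1 = cbg$db1, b2 = cbg$db2)))
  }
  if (v == "cbam") {
    sbg <- spatial_branch_bwd(dout, cache$sb, cache$y1, params, config)
    dy1 <- sbg$dx
    x <- cache$x
    dx <- dy1 * cache$sE
    ds_mat <- dy1 * x
    d <- dim(x); hw <- d[1] * d[2]
    dim(ds_mat) <- c(hw, d[3] * d[4])
    ds <- matrix(colSums(ds_mat), d[3], d[4])
    cbg <- channel_branch_bwd(ds, cache$cb, x, params)
    grads <- list(W1 = cbg$dW1, W2 = cbg$dW2, b1 = cbg$db1, b2 = cbg$db2)
    grads$conv <- sbg$grads$conv
    return(list(dx = dx + cbg$dx, grads = grads))
  }
  # pcsa
  x <- cache$x
  mask <- cache$QP > 0
  dQP <- dout * mask
  dQ <- dQP * cache$P
  dP <- dQP * cache$Q
  # channel branch
  dx <- dQ * cache$sE
  ds_mat <- dQ * x
  d <- dim(x); hw <- d[1] * d[2]
  dim(ds_mat) <- c(hw, d[3] * d[4])
  ds <- matrix(colSums(ds_mat), d[3], d[4])
  cbg <- channel_branch_bwd(ds, cache$cb, x, params)
  dx <- dx + cbg$dx
  # spatial branch
  sbg <- spatial_branch_bwd(dP, cache$sb, x, params, config)
  dx <- dx + sbg$dx
  grads <- list(W1 = cbg$dW1, W2 = cbg$dW2, b1 = cbg$db1, b2 = cbg$db2)
  grads$conv <- sbg$grads$conv
  list(dx = dx, grads = grads)
}
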
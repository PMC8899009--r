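# Residual backbone with attention-augmented bottleneck blocks.
#
# Each bottleneck compresses channels 4x with a 1x1 convolution, processes
# with a 3x3 convolution, re-expands with a 1x1 convolution (each followed by
# batch norm), applies the attention module to the trunk output, adds the
# identity shortcut, and finishes with ReLU. The full classifier is:
# 7x7/2 stem conv + BN + ReLU + 3x3/2 max pool, four stages of blocks
# (default counts 3, 6, 6, 3 with mid widths 64/128/256/512), global average
# pooling, and a dense layer to the class scores.

#' Specification of a single bottleneck block
#'
#' @param in_channels,mid_channels input and compressed channel counts; the
#'   output width is `4 * mid_channels` (the 256 -> 64 -> 256 pattern).
#' @param out_channels output channel count; must equal `4 * mid_channels`.
#' @param stride 1 or 2 (stride of the 3x3 convolution).
#' @param attach_pcsa logical; attach the attention module to the trunk.
#' @param pcsa a [pcsa_config()].
#' @return object of class `bottleneck_spec`.
#' @export
bottleneck_spec <- function(in_channels, mid_channels,
                            out_channels = 4L * mid_channels,
                            stride = 1L, attach_pcsa = TRUE,
                            pcsa = pcsa_config()) {
  if (out_channels != 4L * mid_channels)
    stop("out_channels must equal 4 * mid_channels")
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  structure(list(in_channels = as.integer(in_channels),
                 mid_channels = as.integer(mid_channels),
                 out_channels = as.integer(out_channels),
                 stride = as.integer(stride),
                 attach_pcsa = isTRUE(attach_pcsa),
                 pcsa = pcsa),
            class = "bottleneck_spec")
}

#' Specification of the full classifier network
#'
#' @param stage_blocks integer vector of length 4: number of bottleneck
#'   blocks per stage. Default `c(3, 6, 6, 3)` (18 blocks).
#' @param stem_channels width of the stem convolution (default 64). Stage
#'   mid widths are `stem_channels * c(1, 2, 4, 8)`.
#' @param num_classes number of output classes (default 10, >= 2).
#' @param input_side input image side in pixels (default 224). Must be at
#'   least 32 so the five spatial downsamplings stay valid.
#' @param pcsa a [pcsa_config()] shared by all attention modules.
#' @param attention attention variant attached to every block: `"pcsa"`
#'   (default), `"se"`, `"cbam"`, or `"none"` (the plain residual network).
#' @param placement `"pre_add"` (gate the trunk before the identity addition,
#'   default) or `"post_add"` (gate the block output after addition + ReLU).
#' @param seed integer seed for weight initialization.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(stage_blocks = c(3L, 6L, 6L, 3L),
                         stem_channels = 64L, num_classes = 10L,
                         input_side = 224L, pcsa = pcsa_config(),
                         attention = c("pcsa", "se", "cbam", "none"),
                         placement = c("pre_add", "post_add"),
                         seed = 1L) {
  attention <- match.arg(attention)
  placement <- match.arg(placement)
  stage_blocks <- as.integer(stage_blocks)
  if (length(stage_blocks) != 4L || any(stage_blocks < 1L))
    stop("stage_blocks must be four positive integers")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (input_side < 32L)
    stop("input_side too small: five downsamplings need at least 32 pixels")
  structure(list(stage_blocks = stage_blocks,
                 stem_channels = as.integer(stem_channels),
                 num_classes = as.integer(num_classes),
                 input_side = as.integer(input_side),
                 pcsa = pcsa, attention = attention, placement = placement,
                 seed = as.integer(seed)),
            class = "network_spec")
}

attn_param_init <- function(C, cfg, variant) {
  # reuses pcsa_init's layout without reseeding (caller controls the RNG)
  r <- cfg$reduction_ratio
  if (C %% r != 0L)
    stop(sprintf("attention channels (%d) not divisible by reduction_ratio (%d)",
                 C, r))
  hid <- C %/% r
  params <- list(W1 = he_uniform(c(hid, C), fan_in = C),
                 W2 = he_uniform(c(C, hid), fan_in = hid))
  if (cfg$fc_bias) {
    params$b1 <- numeric(hid)
    params$b2 <- numeric(C)
  }
  if (variant != "se" && cfg$spatial_conv) {
    k <- cfg$spatial_kernel
    ncomb <- if (cfg$spatial_combine == "concat" || variant == "cbam") 2L else 1L
    params$conv <- conv2d_init(k, k, ncomb, 1L, bias = TRUE)
    # start the spatial gate mostly open (M ~ 0.73) so the fused module's
    # early contribution is not doubly attenuated
    params$conv$b[] <- 1
  }
  params
}

block_init <- function(spec, attention, cfg) {
  bp <- list(
    conv1 = conv2d_init(1L, 1L, spec$in_channels, spec$mid_channels),
    bn1 = bn_init(spec$mid_channels),
    conv2 = conv2d_init(3L, 3L, spec$mid_channels, spec$mid_channels),
    bn2 = bn_init(spec$mid_channels),
    conv3 = conv2d_init(1L, 1L, spec$mid_channels, spec$out_channels),
    bn3 = bn_init(spec$out_channels)
  )
  # damped final-BN scale (cf. zero-init-residual): keeps the trunk's early
  # contribution small. Essential here because the attention fusion squares
  # the trunk, which otherwise inflates activation tails double-exponentially
  # with depth in an untrained network. Not exactly zero: the fusion's
  # gradient w.r.t. the trunk vanishes at zero.
  bp$bn3$gamma[] <- 0.5
  if (spec$attach_pcsa && attention != "none")
    bp$attn <- attn_param_init(spec$out_channels, cfg, attention)
  if (spec$stride != 1L || spec$in_channels != spec$out_channels) {
    bp$sc_conv <- conv2d_init(1L, 1L, spec$in_channels, spec$out_channels)
    bp$sc_bn <- bn_init(spec$out_channels)
  }
  bp
}

#' Build a classifier network from a specification
#'
#' After weight initialization the batch-norm running buffers are calibrated
#' with one seeded training-mode forward pass on random inputs (buffers set
#' to the observed batch statistics). Without this, evaluation-mode
#' activations of an untrained network are uncontrolled: the attention
#' fusion squares its input, so unnormalized scales can overflow through a
#' deep stack.
#'
#' @param spec a [network_spec()].
#' @param calibrate logical; perform the buffer-calibration pass
#'   (default TRUE).
#' @return object of class `pcsa_network`: the spec, the initialized
#'   parameters, and a summary (see [model_summary()]).
#' @export
build_network <- function(spec, calibrate = TRUE) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  S <- spec$stem_channels
  mids <- S * c(1L, 2L, 4L, 8L)
  params <- list(stem_conv = conv2d_init(7L, 7L, 3L, S),
                 stem_bn = bn_init(S))
  block_specs <- vector("list", 4L)
  in_ch <- S
  for (st in 1:4) {
    blocks <- vector("list", spec$stage_blocks[st])
    bspecs <- vector("list", spec$stage_blocks[st])
    for (b in seq_len(spec$stage_blocks[st])) {
      bs <- bottleneck_spec(in_ch, mids[st],
                            stride = if (b == 1L && st > 1L) 2L else 1L,
                            attach_pcsa = spec$attention != "none",
                            pcsa = spec$pcsa)
      blocks[[b]] <- block_init(bs, spec$attention, spec$pcsa)
      bspecs[[b]] <- bs
      in_ch <- bs$out_channels
    }
    params[[paste0("stage", st)]] <- blocks
    block_specs[[st]] <- bspecs
  }
  params$fc <- dense_init(in_ch, spec$num_classes)
  model <- structure(list(spec = spec, params = params,
                          block_specs = block_specs),
                     class = "pcsa_network")
  if (calibrate) {
    set.seed(spec$seed + 1L)
    n_cal <- if (spec$input_side > 64L) 1L else 4L
    x <- array(stats::runif(spec$input_side^2 * 3L * n_cal),
               c(spec$input_side, spec$input_side, 3L, n_cal))
    model <- network_forward(model, x, training = TRUE, bn_momentum = 1)$model
  }
  model
}

#' Summarize a built network
#'
#' @param model a `pcsa_network`.
#' @return list with `total_blocks`, `trainable_parameters`, `output_dim`.
#' @export
model_summary <- function(model) {
  list(total_blocks = sum(model$spec$stage_blocks),
       trainable_parameters = count_parameters(model),
       output_dim = model$spec$num_classes)
}

#' Count trainable parameters of a network
#'
#' Batch-norm running statistics are buffers, not parameters, and are
#' excluded.
#'
#' @param model a `pcsa_network`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  count <- function(p, nm = "") {
    if (is.list(p)) {
      nms <- names(p)
      total <- 0L
      for (i in seq_along(p)) {
        total <- total + count(p[[i]], if (is.null(nms)) "" else nms[i])
      }
      total
    } else if (nm %in% c("rm", "rv")) 0L else length(p)
  }
  count(model$params)
}

#' @export
print.pcsa_network <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<pcsa_network> %d blocks (%s attention), %d classes, input %dpx, %s parameters\n",
              s$total_blocks, x$spec$attention, s$output_dim,
              x$spec$input_side, format(s$trainable_parameters, big.mark = ",")))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

block_fwd <- function(x, bp, bspec, spec, training,
                      bn_momentum = BN_MOMENTUM) {
  c1 <- conv2d_fwd(x, bp$conv1, stride = 1L, pad = 0L)
  b1 <- bn_fwd(c1$out, bp$bn1, training, bn_momentum)
  r1 <- relu(b1$out); m1 <- b1$out > 0
  c2 <- conv2d_fwd(r1, bp$conv2, stride = bspec$stride, pad = 1L)
  b2 <- bn_fwd(c2$out, bp$bn2, training, bn_momentum)
  r2 <- relu(b2$out); m2 <- b2$out > 0
  c3 <- conv2d_fwd(r2, bp$conv3, stride = 1L, pad = 0L)
  b3 <- bn_fwd(c3$out, bp$bn3, training, bn_momentum)
  trunk <- b3$out
  if (!is.null(bp$sc_conv)) {
    sc_c <- conv2d_fwd(x, bp$sc_conv, stride = bspec$stride, pad = 0L)
    sc_b <- bn_fwd(sc_c$out, bp$sc_bn, training, bn_momentum)
    sc <- sc_b$out
  } else {
    sc_c <- NULL; sc_b <- NULL
    sc <- x
  }
  variant <- if (is.null(bp$attn)) "none" else spec$attention
  if (spec$placement == "pre_add" || variant == "none") {
    at <- attn_fwd(trunk, bp$attn, spec$pcsa, variant)
    pre <- at$out + sc
    out <- relu(pre); mo <- pre > 0
  } else {
    pre <- trunk + sc
    y0 <- relu(pre); mo <- pre > 0
    at <- attn_fwd(y0, bp$attn, spec$pcsa, variant)
    out <- at$out
  }
  # write back updated BN buffers
  bp$bn1$rm <- b1$rm; bp$bn1$rv <- b1$rv
  bp$bn2$rm <- b2$rm; bp$bn2$rv <- b2$rv
  bp$bn3$rm <- b3$rm; bp$bn3$rv <- b3$rv
  if (!is.null(sc_b)) { bp$sc_bn$rm <- sc_b$rm; bp$sc_bn$rv <- sc_b$rv }
  list(out = out, bp = bp,
       cache = list(c1 = c1$cache, b1 = b1$cache, m1 = m1,
                    c2 = c2$cache, b2 = b2$cache, m2 = m2,
                    c3 = c3$cache, b3 = b3$cache,
                    sc_c = if (!is.null(sc_c)) sc_c$cache else NULL,
                    sc_b = if (!is.null(sc_b)) sc_b$cache else NULL,
                    at = at$cache, mo = mo, variant = variant))
}

block_bwd <- function(dout, cache, bp, spec) {
  g <- list()
  if (spec$placement == "pre_add" || cache$variant == "none") {
    dpre <- dout * cache$mo
    ab <- attn_bwd(dpre, cache$at, bp$attn, spec$pcsa)
    dtrunk <- ab$dx
    dsc <- dpre
  } else {
    ab <- attn_bwd(dout, cache$at, bp$attn, spec$pcsa)
    dpre <- ab$dx * cache$mo
    dtrunk <- dpre
    dsc <- dpre
  }
  if (length(ab$grads)) g$attn <- ab$grads
  b3 <- bn_bwd(dtrunk, cache$b3, bp$bn3)
  g$bn3 <- list(gamma = b3$dgamma, beta = b3$dbeta)
  c3 <- conv2d_bwd(b3$dx, cache$c3, bp$conv3)
  g$conv3 <- list(W = c3$dW)
  dr2 <- c3$dx * cache$m2
  b2 <- bn_bwd(dr2, cache$b2, bp$bn2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  c2 <- conv2d_bwd(b2$dx, cache$c2, bp$conv2)
  g$conv2 <- list(W = c2$dW)
  dr1 <- c2$dx * cache$m1
  b1 <- bn_bwd(dr1, cache$b1, bp$bn1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  c1 <- conv2d_bwd(b1$dx, cache$c1, bp$conv1)
  g$conv1 <- list(W = c1$dW)
  dx <- c1$dx
  if (!is.null(cache$sc_c)) {
    sb <- bn_bwd(dsc, cache$sc_b, bp$sc_bn)
    g$sc_bn <- list(gamma = sb$dgamma, beta = sb$dbeta)
    sc <- conv2d_bwd(sb$dx, cache$sc_c, bp$sc_conv)
    g$sc_conv <- list(W = sc$dW)
    dx <- dx + sc$dx
  } else {
    dx <- dx + dsc
  }
  list(dx = dx, grads = g)
}

#' Forward pass of a built network
#'
#' @param model a `pcsa_network`.
#' @param x numeric array `(H, W, 3, N)` of inputs in `[0, 1]`.
#' @param training logical; use batch statistics (and update running
#'   statistics) in batch norm when TRUE.
#' @return list with `logits` (`num_classes x N` score matrix), `caches`
#'   (for the backward pass), and `model` (with updated BN buffers when
#'   training).
#' @export
network_forward <- function(model, x, training = FALSE,
                            bn_momentum = BN_MOMENTUM) {
  spec <- model$spec
  d <- dim(x)
  if (length(d) != 4L || d[3] != 3L)
    stop("input must be an (H, W, 3, N) array")
  if (d[1] != spec$input_side || d[2] != spec$input_side)
    stop(sprintf("input side %dx%d does not match the network's input_side %d",
                 d[1], d[2], spec$input_side))
  p <- model$params
  sc <- conv2d_fwd(x, p$stem_conv, stride = 2L, pad = 3L)
  sb <- bn_fwd(sc$out, p$stem_bn, training, bn_momentum)
  sr <- relu(sb$out); sm <- sb$out > 0
  mp <- maxpool_fwd(sr, k = 3L, stride = 2L, pad = 1L)
  p$stem_bn$rm <- sb$rm; p$stem_bn$rv <- sb$rv
  h <- mp$out
  caches <- list(stem = list(conv = sc$cache, bn = sb$cache, mask = sm,
                             pool = mp$cache))
  for (st in 1:4) {
    stage_name <- paste0("stage", st)
    scaches <- vector("list", length(p[[stage_name]]))
    for (b in seq_along(p[[stage_name]])) {
      bf <- block_fwd(h, p[[stage_name]][[b]], model$block_specs[[st]][[b]],
                      spec, training, bn_momentum)
      h <- bf$out
      p[[stage_name]][[b]] <- bf$bp
      scaches[[b]] <- bf$cache
    }
    caches[[stage_name]] <- scaches
  }
  gp <- global_avgpool_fwd(h)
  fc <- dense_fwd(gp$out, p$fc)
  caches$gap_dim <- gp$cache
  caches$fc_in <- fc$cache
  model$params <- p
  list(logits = fc$out, caches = caches, model = model)
}

#' Backward pass (gradients of a loss w.r.t. all parameters)
#'
#' @param dlogits gradient of the loss w.r.t. the logits (`K x N`).
#' @param caches the `caches` element returned by [network_forward()].
#' @param model the `pcsa_network` the forward pass ran on.
#' @return nested list of gradients mirroring `model$params` (BN buffers
#'   excluded), plus `dx` (gradient w.r.t. the input batch).
#' @export
network_backward <- function(dlogits, caches, model) {
  p <- model$params
  spec <- model$spec
  g <- list()
  fcb <- dense_bwd(dlogits, caches$fc_in, p$fc)
  g$fc <- list(W = fcb$dW, b = fcb$db)
  dh <- global_avgpool_bwd(fcb$dx, caches$gap_dim)
  for (st in 4:1) {
    stage_name <- paste0("stage", st)
    nb <- length(p[[stage_name]])
    sg <- vector("list", nb)
    for (b in nb:1) {
      bb <- block_bwd(dh, caches[[stage_name]][[b]], p[[stage_name]][[b]], spec)
      dh <- bb$dx
      sg[[b]] <- bb$grads
    }
    g[[stage_name]] <- sg
  }
  dpool <- maxpool_bwd(dh, caches$stem$pool)
  dsr <- dpool * caches$stem$mask
  sb <- bn_bwd(dsr, caches$stem$bn, p$stem_bn)
  g$stem_bn <- list(gamma = sb$dgamma, beta = sb$dbeta)
  scv <- conv2d_bwd(sb$dx, caches$stem$conv, p$stem_conv)
  g$stem_conv <- list(W = scv$dW)
  g$dx <- scv$dx
  g
}

#' Classify a batch of images
#'
#' @param model a `pcsa_network`.
#' @param images numeric array `(H, W, 3, N)`; 8-bit integer pixel values are
#'   rescaled to `[0, 1]` automatically.
#' @return `N x num_classes` matrix of softmax probabilities; each row sums
#'   to 1.
#' @export
forward_classify <- function(model, images) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (max(images) > 1.5) images <- images / 255
  logits <- network_forward(model, images, training = FALSE)$logits
  t(softmax_cols(logits))
}

#' Zero every trunk convolution of a network
#'
#' With the trunk convolutions zeroed, batch norm outputs its beta (zero at
#' initialization), the attention of a zero map is zero, and every block
#' reduces to `relu(shortcut)` -- a useful degenerate limit for testing the
#' residual wiring.
#'
#' @param model a `pcsa_network`.
#' @return the modified network.
#' @export
zero_trunk_weights <- function(model) {
  for (st in 1:4) {
    stage_name <- paste0("stage", st)
    for (b in seq_along(model$params[[stage_name]])) {
      for (cv in c("conv1", "conv2", "conv3")) {
        model$params[[stage_name]][[b]][[cv]]$W[] <- 0
      }
      for (bn in c("bn1", "bn2", "bn3")) {
        model$params[[stage_name]][[b]][[bn]]$rm[] <- 0
        model$params[[stage_name]][[b]][[bn]]$beta[] <- 0
      }
    }
  }
  model
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' A single-file archive holding the weights (including BN buffers), the
#' network specification, and the epoch / validation accuracy it was saved
#' at.
#'
#' @param model a `pcsa_network`.
#' @param path file path.
#' @param epoch,val_accuracy optional provenance of the checkpoint.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_,
                            val_accuracy = NA_real_) {
  saveRDS(list(spec = model$spec, params = model$params,
               block_specs = model$block_specs,
               epoch = epoch, val_accuracy = val_accuracy,
               package_version = as.character(utils::packageVersion("pcsanet"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file path written by [save_checkpoint()].
#' @return list with `model` (a `pcsa_network`), `epoch`, `val_accuracy`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(spec = ck$spec, params = ck$params,
                          block_specs = ck$block_specs),
                     class = "pcsa_network")
  list(model = model, epoch = ck$epoch, val_accuracy = ck$val_accuracy)
}
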
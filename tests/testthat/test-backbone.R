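# Bottleneck blocks and the assembled classifier.

tiny_spec <- function(attention = "pcsa", seed = 1L, ...) {
  network_spec(stage_blocks = c(1L, 1L, 1L, 1L), stem_channels = 16L,
               num_classes = 3L, input_side = 32L,
               pcsa = pcsa_config(reduction_ratio = 16L, spatial_kernel = 7L,
                                  seed = seed),
               attention = attention, seed = seed, ...)
}

test_that("bottleneck specs enforce the 4x expansion and stride domain", {
  s <- bottleneck_spec(256, 64)
  expect_identical(s$out_channels, 256L)
  expect_error(bottleneck_spec(256, 64, out_channels = 128), "4 \\* mid")
  expect_error(bottleneck_spec(256, 64, stride = 3), "stride")
  expect_error(network_spec(stage_blocks = c(3, 6, 6)), "four")
  expect_error(network_spec(num_classes = 1), "num_classes")
  expect_error(network_spec(input_side = 16), "too small")
})

test_that("the trunk compresses 256 -> 64 -> 64 -> 256 channels", {
  set.seed(1)
  bs <- bottleneck_spec(256, 64, attach_pcsa = FALSE)
  bp <- pcsanet:::block_init(bs, "none", pcsa_config())
  expect_identical(dim(bp$conv1$W), c(1L, 1L, 256L, 64L))
  expect_identical(dim(bp$conv2$W), c(3L, 3L, 64L, 64L))
  expect_identical(dim(bp$conv3$W), c(1L, 1L, 64L, 256L))
})

test_that("a stride-2 block halves the spatial side and sets out channels", {
  set.seed(2)
  bs <- bottleneck_spec(256, 64, stride = 2, attach_pcsa = FALSE)
  bp <- pcsanet:::block_init(bs, "none", pcsa_config())
  spec <- tiny_spec("none")
  x <- array(stats::rnorm(8 * 8 * 256), c(8, 8, 256, 1))
  out <- pcsanet:::block_fwd(x, bp, bs, spec, training = FALSE)$out
  # floor((8 - 1) / 2) + 1 = 4
  expect_identical(dim(out), c(4L, 4L, 256L, 1L))
})

test_that("zero-trunk blocks reduce to relu(identity)", {
  model <- build_network(tiny_spec("pcsa"))
  model <- zero_trunk_weights(model)
  # isolate one identity-shortcut block (stage 1 has in == out after its
  # first projection block, so use a two-block stage)
  spec2 <- network_spec(stage_blocks = c(2L, 1L, 1L, 1L), stem_channels = 16L,
                        num_classes = 3L, input_side = 32L,
                        pcsa = pcsa_config(seed = 1), attention = "pcsa",
                        seed = 1)
  m2 <- zero_trunk_weights(build_network(spec2))
  bp <- m2$params$stage1[[2]]          # identity shortcut, stride 1
  bs <- m2$block_specs[[1]][[2]]
  x <- array(stats::rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  out <- pcsanet:::block_fwd(x, bp, bs, m2$spec, training = FALSE)$out
  expect_equal(out, pmax(x, 0), tolerance = 1e-12)
})

test_that("network summary counts blocks and output dimension", {
  m <- build_network(tiny_spec())
  s <- model_summary(m)
  expect_identical(s$total_blocks, 4L)
  expect_identical(s$output_dim, 3L)
  expect_identical(s$trainable_parameters, count_parameters(m))
})

test_that("attention on/off parameter difference equals the module formula", {
  spec_on <- tiny_spec("pcsa")
  spec_off <- tiny_spec("none")
  n_on <- count_parameters(build_network(spec_on))
  n_off <- count_parameters(build_network(spec_off))
  # per-block attention operates on the stage output width C = 4 * mid
  widths <- 16L * c(1L, 2L, 4L, 8L) * 4L
  expected <- sum(spec_on$stage_blocks *
                    (2 * widths^2 / 16 + 7^2 + 1))
  expect_identical(n_on - n_off, as.integer(expected))
})

test_that("classification output is a softmax row per image", {
  m <- build_network(tiny_spec())
  set.seed(9)
  imgs <- array(stats::runif(32 * 32 * 3 * 3), c(32, 32, 3, 3))
  imgs[, , , 3] <- imgs[, , , 1]      # duplicate of image 1
  probs <- forward_classify(m, imgs)
  expect_identical(dim(probs), c(3L, 3L))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  # determinism in eval mode: identical images -> identical rows
  expect_equal(probs[1, ], probs[3, ], tolerance = 1e-12)
  # batch equivariance: permuting the batch permutes the rows
  probs2 <- forward_classify(m, imgs[, , , c(2, 1, 3)])
  expect_equal(probs2, probs[c(2, 1, 3), ], tolerance = 1e-12)
  expect_error(forward_classify(m, array(0, c(16, 16, 3, 1))), "side")
})

test_that("checkpoint round-trip is bit-identical in eval mode", {
  m <- build_network(tiny_spec())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, epoch = 7L, val_accuracy = 0.5)
  ck <- load_checkpoint(path)
  expect_identical(ck$epoch, 7L)
  set.seed(12)
  x <- array(stats::runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_identical(network_forward(m, x)$logits,
                   network_forward(ck$model, x)$logits)
  unlink(path)
})

test_that("network gradients flow to every parameter group", {
  m <- build_network(tiny_spec())
  set.seed(21)
  x <- array(stats::runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fwd <- network_forward(m, x, training = TRUE)
  ce <- pcsanet:::softmax_xent(fwd$logits, c(0L, 2L))
  g <- network_backward(ce$dlogits, fwd$caches, fwd$model)
  expect_gt(sum(abs(g$stem_conv$W)), 0)
  expect_gt(sum(abs(g$fc$W)), 0)
  for (st in 1:4) {
    blk <- g[[paste0("stage", st)]][[1]]
    expect_gt(sum(abs(blk$conv2$W)), 0)
    expect_gt(sum(abs(blk$attn$W1)), 0)
    expect_true(all(is.finite(blk$conv2$W)))
  }
})
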
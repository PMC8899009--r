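# Attention module: squeeze / excite / scale, spatial gate, parallel fusion.

test_that("squeeze matches the global-average-pooling definition", {
  f <- array(3.7, c(4, 5, 6))
  expect_equal(squeeze(f), rep(3.7, 4))

  f1 <- array(c(1, 2, 3, 4), c(1, 2, 2))
  expect_equal(squeeze(f1), 2.5)

  f2 <- rand_cwh(3, 5, 5, seed = 101)
  expect_equal(squeeze(f2), loop_squeeze(f2), tolerance = 1e-12)

  expect_error(squeeze(1:3), "3-d array")
})

test_that("excite is the sigmoid-gated two-layer map and stays in (0,1)", {
  cfg <- pcsa_config(reduction_ratio = 2, seed = 5)
  mod <- pcsa_init(4, cfg)
  # zero descriptor with no biases: sigmoid(0) everywhere
  expect_equal(excite(numeric(4), mod), rep(0.5, 4))

  set.seed(42)
  for (i in 1:20) {
    s <- excite(stats::rnorm(4, sd = 2), mod)
    expect_true(all(s > 0 & s < 1))
  }

  z <- c(0.3, -1.2, 2.2, 0.4)
  expect_equal(excite(z, mod),
               loop_excite(z, mod$params$W1, mod$params$W2),
               tolerance = 1e-12)

  expect_error(excite(numeric(5), mod), "does not match")
})

test_that("channel_scale rescales per channel and preserves shape", {
  f <- rand_cwh(3, 4, 4, seed = 7)
  expect_identical(channel_scale(f, rep(1, 3)), f)

  s <- c(0.5, 0, 2)
  out <- channel_scale(f, s)
  expect_true(all(out[2, , ] == 0))
  expect_equal(out[1, , ], 0.5 * f[1, , ])
  expect_equal(out, loop_channel_scale(f, s), tolerance = 1e-12)

  expect_error(channel_scale(f, rep(1, 4)), "does not match")
})

test_that("spatial gate pools across channels, fuses and gates in (0,1)", {
  cfg <- pcsa_config(reduction_ratio = 1, spatial_kernel = 3, seed = 9)
  mod <- pcsa_init(2, cfg)
  f <- rand_cwh(2, 3, 3, seed = 33)

  # pooling maps against the per-pixel loop oracle
  x <- aperm(array(f, c(dim(f), 1L)), c(2, 3, 1, 4))
  sb <- pcsanet:::spatial_branch_fwd(x, mod$params, cfg)
  pools <- loop_pool_maps(f)
  expect_equal(matrix(sb$cache$favg, 3, 3), pools$avg, tolerance = 1e-12)
  expect_equal(matrix(sb$cache$fmax, 3, 3), pools$max, tolerance = 1e-12)

  # single-channel input: both pooling maps are the channel itself
  mod1 <- pcsa_init(1, cfg)
  f1 <- rand_cwh(1, 4, 4, seed = 8)
  x1 <- aperm(array(f1, c(dim(f1), 1L)), c(2, 3, 1, 4))
  sb1 <- pcsanet:::spatial_branch_fwd(x1, mod1$params, cfg)
  expect_equal(matrix(sb1$cache$favg, 4, 4), f1[1, , ], tolerance = 1e-12)
  expect_equal(matrix(sb1$cache$fmax, 4, 4), f1[1, , ], tolerance = 1e-12)

  # full gate: M strictly in (0,1), P has f's shape, and M matches the
  # loop-convolution oracle on the combined map
  res <- spatial_gate(f, mod)
  expect_true(all(res$M > 0 & res$M < 1))
  expect_identical(dim(res$P), dim(f))
  comb <- array(pools$avg * pools$max, c(3, 3, 1))
  m_oracle <- 1 / (1 + exp(-loop_conv2d_same(comb, mod$params$conv$W,
                                             mod$params$conv$b)))
  expect_equal(matrix(res$M[1, , ], 3, 3), m_oracle, tolerance = 1e-10)
  expect_equal(res$P, f * rep(res$M[1, , ], each = 2), tolerance = 1e-12)

  expect_error(pcsa_config(spatial_kernel = 4), "odd")
})

test_that("parallel fusion composes the two branches and is non-negative", {
  cfg <- pcsa_config(reduction_ratio = 2, spatial_kernel = 3, seed = 21)
  mod <- pcsa_init(4, cfg)

  z4 <- array(0, c(4, 5, 5))
  expect_equal(pcsa_forward(z4, mod), z4)

  f <- rand_cwh(4, 5, 5, seed = 55)
  g <- pcsa_forward(f, mod)
  expect_identical(dim(g), dim(f))
  expect_true(min(g) >= 0)

  # composed-oracle equivalence: recompute each branch with the loop
  # oracles, fuse by elementwise product + relu
  s <- loop_excite(loop_squeeze(f), mod$params$W1, mod$params$W2)
  Q <- loop_channel_scale(f, s)
  pools <- loop_pool_maps(f)
  comb <- array(pools$avg * pools$max, c(5, 5, 1))
  M <- 1 / (1 + exp(-loop_conv2d_same(comb, mod$params$conv$W,
                                      mod$params$conv$b)))
  P <- f * rep(M, each = 4)
  G <- pmax(Q * P, 0)
  expect_equal(g, G, tolerance = 1e-10)

  expect_error(pcsa_forward(rand_cwh(6, 5, 5, 1), mod), "channels")
})

test_that("gate outputs stay strictly inside (0,1) over many random maps", {
  cfg <- pcsa_config(reduction_ratio = 4, spatial_kernel = 3, seed = 2)
  mod <- pcsa_init(8, cfg)
  for (i in 1:100) {
    f <- rand_cwh(8, 4, 4, seed = 1000 + i)
    s <- excite(squeeze(f), mod)
    expect_true(all(s > 0 & s < 1))
    M <- spatial_gate(f, mod)$M
    expect_true(all(M > 0 & M < 1))
  }
})

test_that("module parameter count is 2C^2/r + k^2 + 1", {
  for (C in c(16, 32, 64)) {
    mod <- pcsa_init(C, pcsa_config(reduction_ratio = 16, spatial_kernel = 7,
                                    seed = 1))
    expect_identical(pcsa_param_count(mod), as.integer(2 * C^2 / 16 + 49 + 1))
  }
  mod3 <- pcsa_init(8, pcsa_config(reduction_ratio = 2, spatial_kernel = 3,
                                   seed = 1))
  expect_identical(pcsa_param_count(mod3), as.integer(2 * 64 / 2 + 9 + 1))
  expect_error(pcsa_init(10, pcsa_config(reduction_ratio = 16)), "divisible")
})

test_that("attention gradients are finite, non-zero, and match finite differences", {
  cfg <- pcsa_config(reduction_ratio = 2, spatial_kernel = 3, seed = 13)
  for (variant in c("pcsa", "se", "cbam")) {
    mod <- pcsa_init(4, cfg, variant)
    set.seed(99)
    x <- array(stats::rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
    fwd <- pcsanet:::attn_fwd(x, mod$params, cfg, variant)
    dout <- cos(fwd$out)
    bk <- pcsanet:::attn_bwd(dout, fwd$cache, mod$params, cfg)
    expect_true(all(is.finite(bk$dx)))
    expect_gt(sum(abs(bk$dx)), 0)
    expect_gt(sum(abs(bk$grads$W1)), 0)
    loss <- function(xx) sum(sin(pcsanet:::attn_fwd(xx, mod$params, cfg,
                                                    variant)$out))
    idx <- sample(length(x), 5)
    num <- sapply(idx, function(i) {
      xp <- x; xp[i] <- xp[i] + 1e-5
      xm <- x; xm[i] <- xm[i] - 1e-5
      (loss(xp) - loss(xm)) / 2e-5
    })
    expect_equal(num, bk$dx[idx], tolerance = 1e-4)
  }
})

test_that("forcing both gates open reduces the fusion to relu(f * f)", {
  # With the excitation weights all one and the spatial map all one the
  # fusion is relu(Q * P) = relu(f * f): the parallel product acts on two
  # gated copies of the same input, so the open-gate limit squares the map
  # rather than reproducing it.
  f <- rand_cwh(3, 4, 4, seed = 3)
  Q <- channel_scale(f, rep(1, 3))
  P <- f * 1
  expect_equal(pmax(Q * P, 0), pmax(f * f, 0))
})
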
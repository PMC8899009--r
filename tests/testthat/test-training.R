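# SGDM update rule, plateau schedule, and the training loop.

test_that("sgdm_step implements the previous-iterate update rule", {
  # hand value: theta_i = 1.0, theta_{i-1} = 0.9, g = 0.5, lr = 0.1, m = 0.1
  # -> 1.0 - 0.05 + 0.1 * 0.1 = 0.96
  st <- sgdm_state(1.0)
  st$theta_prev <- 0.9
  st <- sgdm_step(st, grad = 0.5, lr = 0.1, momentum = 0.1)
  expect_equal(st$theta, 0.96, tolerance = 1e-12)
  expect_identical(st$iter, 1L)

  # fixed point: zero gradient and no history leaves theta unchanged
  st0 <- sgdm_step(sgdm_state(c(1, 2, 3)), grad = c(0, 0, 0),
                   lr = 0.1, momentum = 0.5)
  expect_equal(st0$theta, c(1, 2, 3))

  # momentum-off limit: plain gradient step
  st1 <- sgdm_step(sgdm_state(c(1, 2)), grad = c(1, -1), lr = 0.25,
                   momentum = 0)
  expect_equal(st1$theta, c(0.75, 2.25))

  # weight decay folds into the gradient before the update
  st2 <- sgdm_step(sgdm_state(2), grad = 0, lr = 0.1, momentum = 0,
                   weight_decay = 0.5)
  expect_equal(st2$theta, 2 - 0.1 * (0.5 * 2))

  expect_error(sgdm_step(sgdm_state(c(1, 2)), grad = c(1, 2, 3),
                         lr = 0.1, momentum = 0), "shape")
})

test_that("previous-iterate SGDM equals velocity-form momentum", {
  set.seed(17)
  theta <- stats::rnorm(6)
  st <- sgdm_state(theta)
  v <- numeric(6)
  th_v <- theta
  for (i in 1:25) {
    g <- stats::rnorm(6)
    st <- sgdm_step(st, g, lr = 0.05, momentum = 0.9)
    v <- 0.9 * v - 0.05 * g
    th_v <- th_v + v
    expect_equal(st$theta, th_v, tolerance = 1e-12)
  }
})

test_that("sgdm_step works on nested parameter lists", {
  theta <- list(a = matrix(1:4, 2), b = list(c = c(0.5, -0.5)))
  grad <- list(a = matrix(1, 2, 2), b = list(c = c(1, 1)))
  st <- sgdm_step(sgdm_state(theta), grad, lr = 0.1, momentum = 0)
  expect_equal(st$theta$a, matrix(1:4, 2) - 0.1)
  expect_equal(st$theta$b$c, c(0.4, -0.6))
})

test_that("the plateau rule decays only after patience epochs without improvement", {
  # monotone improvement: never decays
  expect_equal(plateau_lr_trace(c(0.1, 0.2, 0.3, 0.4), 1e-3, 2, 0.1),
               rep(1e-3, 4))
  # flat for exactly `patience` epochs: one decay
  expect_equal(plateau_lr_trace(c(0.5, 0.5, 0.5), 1e-3, 2, 0.1),
               c(1e-3, 1e-3, 1e-4))
  # decays fire after epochs 3 and 6
  tr <- plateau_lr_trace(c(0.5, 0.5, 0.5, 0.6, 0.6, 0.6), 1e-3, 2, 0.1)
  expect_equal(tr, c(1e-3, 1e-3, 1e-4, 1e-4, 1e-4, 1e-5))
  cfg <- train_config()
  expect_equal(lr_schedule_step(c(0.5, 0.5, 0.5), cfg), 1e-4)
  expect_error(train_config(lr_decay_factor = 1.5), "lr_decay_factor")
  expect_error(train_config(momentum = 1), "momentum")
})

# trivially separable two-class data: full-image colour difference
easy_data <- function(n_per_class, seed) {
  set.seed(seed)
  mk <- function(n, ch) {
    x <- array(stats::runif(32 * 32 * 3 * n, 0, 0.3), c(32, 32, 3, n))
    x[, , ch, ] <- x[, , ch, ] + 0.6
    x
  }
  x <- array(0, c(32, 32, 3, 2 * n_per_class))
  x[, , , seq_len(n_per_class)] <- mk(n_per_class, 1)
  x[, , , n_per_class + seq_len(n_per_class)] <- mk(n_per_class, 3)
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

easy_spec <- function(seed) {
  network_spec(stage_blocks = c(1L, 1L, 1L, 1L), stem_channels = 16L,
               num_classes = 2L, input_side = 32L,
               pcsa = pcsa_config(seed = seed), attention = "pcsa",
               seed = seed)
}

test_that("a frozen run (learning rate 0) leaves the weights untouched", {
  tr <- easy_data(6, seed = 1)
  va <- easy_data(3, seed = 2)
  model <- build_network(easy_spec(1))
  cfg <- train_config(learning_rate = 0, momentum = 0, epochs = 1L,
                      batch_size = 6L, seed = 1)
  res <- fit(model, tr, va, cfg)
  expect_identical(res$final_model$params$fc$W, model$params$fc$W)
  expect_identical(res$final_model$params$stage3[[1]]$conv2$W,
                   model$params$stage3[[1]]$conv2$W)
  # batch-norm running statistics are buffers, not weights: they still track
  # the data in a frozen run, so the logged accuracy is the frozen model's
  # accuracy under its final buffers
  expect_equal(res$log$val_accuracy,
               pcsanet:::model_accuracy(res$final_model, va))
  expect_identical(res$log$lr, 0)
})

test_that("training is reproducible and reduces the loss on a separable task", {
  tr <- easy_data(10, seed = 3)
  va <- easy_data(5, seed = 4)
  cfg <- train_config(learning_rate = 0.02, momentum = 0.9,
                      weight_decay = 1e-5, epochs = 3L, batch_size = 10L,
                      clip_grad_norm = 5, seed = 7)
  r1 <- fit(build_network(easy_spec(2)), tr, va, cfg)
  r2 <- fit(build_network(easy_spec(2)), tr, va, cfg)
  expect_identical(r1$log, r2$log)
  expect_lt(r1$log$loss[3], r1$log$loss[1])
  # the returned checkpoint is the arg-max of the validation trace
  expect_equal(r1$best_val_accuracy, max(r1$log$val_accuracy))
  expect_identical(r1$best_epoch,
                   which.max(r1$log$val_accuracy))
  # learning rate never increases across a run
  expect_true(all(diff(r1$log$lr) <= 0))
  expect_error(fit(build_network(easy_spec(2)),
                   list(x = tr$x[, , , 0], y = integer(0)), va, cfg),
               "non-empty")
})
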
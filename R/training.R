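# Training: stochastic gradient descent with momentum (SGDM), a plateau
# learning-rate schedule, per-epoch shuffling, and best-checkpoint selection.
#
# The parameter update follows
#   theta_{i+1} = theta_i - alpha * grad(theta_i) + m * (theta_i - theta_{i-1})
# with L2 weight decay folded into the gradient before the update. The
# previous-iterate difference theta_i - theta_{i-1} equals the classical
# momentum velocity, so the training loop keeps a velocity buffer
# v <- m * v - alpha * g; theta <- theta + v, which is algebraically the same
# rule (a property the test suite asserts numerically).

#' Training configuration
#'
#' Defaults follow the reference training setup: initial learning rate 1e-3,
#' weight decay 1e-5, momentum 0.1, 100 epochs, and a learning-rate decay by
#' 0.1 whenever validation accuracy fails to improve for 2 consecutive
#' epochs. (A momentum of 0.1 is unusually low for SGDM but is the stated
#' setting; it is configurable.)
#'
#' @param learning_rate initial learning rate alpha (> 0).
#' @param weight_decay L2 coefficient lambda (>= 0).
#' @param momentum momentum factor m in [0, 1).
#' @param epochs number of training epochs.
#' @param plateau_patience epochs without validation-accuracy improvement
#'   before the learning rate decays.
#' @param lr_decay_factor multiplicative decay factor in (0, 1).
#' @param batch_size minibatch size.
#' @param clip_grad_norm global gradient-norm ceiling; gradients are scaled
#'   down when their global L2 norm exceeds it (default `Inf`, no clipping).
#' @param seed integer seed governing shuffling (and any other randomness in
#'   the run).
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.00001,
                         momentum = 0.1, epochs = 100L,
                         plateau_patience = 2L, lr_decay_factor = 0.1,
                         batch_size = 32L, clip_grad_norm = Inf, seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  if (lr_decay_factor <= 0 || lr_decay_factor >= 1)
    stop("lr_decay_factor must lie strictly in (0, 1)")
  if (weight_decay < 0) stop("weight_decay must be non-negative")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, epochs = as.integer(epochs),
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 clip_grad_norm = clip_grad_norm, seed = as.integer(seed)),
            class = "train_config")
}

#' Optimizer state for the previous-iterate form of SGDM
#'
#' @param theta initial parameters: a numeric vector/array, or a (nested)
#'   list of them.
#' @return object of class `sgdm_state` holding `theta`, `theta_prev` (equal
#'   to `theta` initially, so the first step has no momentum term) and the
#'   iteration counter.
#' @export
sgdm_state <- function(theta) {
  structure(list(theta = theta, theta_prev = theta, iter = 0L),
            class = "sgdm_state")
}

sgdm_update_leaf <- function(theta, theta_prev, grad, lr, momentum,
                             weight_decay) {
  if (is.list(theta))
    return(Map(sgdm_update_leaf, theta, theta_prev, grad,
               MoreArgs = list(lr = lr, momentum = momentum,
                               weight_decay = weight_decay)))
  if (!identical(dim(theta), dim(grad)) || length(theta) != length(grad))
    stop("gradient shape does not match parameter shape")
  g <- grad + weight_decay * theta
  theta - lr * g + momentum * (theta - theta_prev)
}

#' One SGDM parameter update
#'
#' Applies `theta_{i+1} = theta_i - lr * (grad + wd * theta_i) +
#' momentum * (theta_i - theta_{i-1})` and advances the state.
#'
#' @param state an [sgdm_state()].
#' @param grad gradient with the same structure/shape as `state$theta`.
#' @param lr learning rate.
#' @param momentum momentum factor.
#' @param weight_decay L2 coefficient added to the gradient before the
#'   update (default 0).
#' @return the updated `sgdm_state`.
#' @export
sgdm_step <- function(state, grad, lr, momentum, weight_decay = 0) {
  stopifnot(inherits(state, "sgdm_state"))
  theta_next <- sgdm_update_leaf(state$theta, state$theta_prev, grad,
                                 lr, momentum, weight_decay)
  structure(list(theta = theta_next, theta_prev = state$theta,
                 iter = state$iter + 1L),
            class = "sgdm_state")
}

#' Learning-rate trace under the plateau rule
#'
#' Steps through a validation-accuracy history: whenever the accuracy has
#' not improved on the best seen so far for `patience` consecutive epochs,
#' the learning rate is multiplied by `factor` and the counter resets.
#'
#' @param val_accuracy numeric vector of per-epoch validation accuracies.
#' @param initial_lr learning rate before epoch 1.
#' @param patience plateau patience in epochs.
#' @param factor decay factor in (0, 1).
#' @return numeric vector: the learning rate in force AFTER each epoch.
#' @export
plateau_lr_trace <- function(val_accuracy, initial_lr, patience = 2L,
                             factor = 0.1) {
  lr <- initial_lr
  best <- -Inf
  counter <- 0L
  out <- numeric(length(val_accuracy))
  for (e in seq_along(val_accuracy)) {
    if (val_accuracy[e] > best) {
      best <- val_accuracy[e]
      counter <- 0L
    } else {
      counter <- counter + 1L
      if (counter >= patience) {
        lr <- lr * factor
        counter <- 0L
      }
    }
    out[e] <- lr
  }
  out
}

#' Next learning rate given a training log
#'
#' @param val_accuracy validation-accuracy history (>= 1 epoch).
#' @param cfg a [train_config()].
#' @return the learning rate for the next epoch.
#' @export
lr_schedule_step <- function(val_accuracy, cfg) {
  stopifnot(length(val_accuracy) >= 1L)
  tr <- plateau_lr_trace(val_accuracy, cfg$learning_rate,
                         cfg$plateau_patience, cfg$lr_decay_factor)
  tr[length(tr)]
}

# Recursive velocity-form SGDM update over the nested parameter/grad lists.
# Returns list(params, velocity). BN running stats never appear in grads, so
# they are left untouched.
update_params_rec <- function(params, grads, vel, lr, momentum, wd) {
  if (is.null(vel)) vel <- vector("list", length(grads))
  if (length(vel) < length(grads)) length(vel) <- length(grads)
  keys <- names(grads)
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    key <- if (!is.null(keys) && nzchar(keys[i])) keys[i] else i
    if (is.list(g)) {
      res <- update_params_rec(params[[key]], g, vel[[i]], lr, momentum, wd)
      params[[key]] <- res$params
      vel[[i]] <- res$vel
    } else {
      p <- params[[key]]
      v <- vel[[i]]
      if (is.null(v)) v <- p * 0
      v <- momentum * v - lr * (g + wd * p)
      params[[key]] <- p + v
      vel[[i]] <- v
    }
  }
  list(params = params, vel = vel)
}

grad_global_norm <- function(grads) {
  sqrt(sum(unlist(lapply(grads, function(g)
    if (is.list(g)) grad_global_norm(g)^2 else sum(g * g)))))
}

scale_grads <- function(grads, fac) {
  lapply(grads, function(g) {
    if (is.null(g)) NULL
    else if (is.list(g)) scale_grads(g, fac)
    else g * fac
  })
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

model_accuracy <- function(model, data, batch_size = 64L) {
  n <- length(data$y)
  correct <- 0L
  for (idx in batch_indices(n, batch_size)) {
    logits <- network_forward(model, data$x[, , , idx, drop = FALSE],
                              training = FALSE)$logits
    pred <- max.col(t(logits), ties.method = "first") - 1L
    correct <- correct + sum(pred == data$y[idx])
  }
  correct / n
}

#' Train a network with SGDM and best-checkpoint selection
#'
#' Per epoch: seeded shuffle of the training set, minibatch SGDM over
#' softmax cross-entropy, a full validation pass, checkpointing whenever the
#' validation accuracy improves on the best so far, and the plateau
#' learning-rate rule. The model returned is the best-validation-accuracy
#' checkpoint, not the final iterate.
#'
#' @param model a `pcsa_network` (see [build_network()]).
#' @param train_data,val_data lists with `x` (`(H, W, 3, N)` array in
#'   `[0, 1]`) and `y` (0-based labels), e.g. from [as_image_batch()] or
#'   [load_split()]. The two sets must be disjoint splits.
#' @param cfg a [train_config()].
#' @param checkpoint_dir optional directory; when given, the best checkpoint
#'   is also written there as `best.rds` and the log as `train_log.csv`.
#' @param verbose print one line per epoch.
#' @return list with `model` (best checkpoint), `log` (data frame with
#'   epoch, train loss, validation accuracy, learning rate), `best_epoch`,
#'   `best_val_accuracy`, and `final_model`.
#' @export
fit <- function(model, train_data, val_data, cfg = train_config(),
                checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  n <- length(train_data$y)
  if (n == 0L || length(val_data$y) == 0L)
    stop("train and validation splits must be non-empty")
  if (max(train_data$x) > 1.5) train_data$x <- train_data$x / 255
  if (max(val_data$x) > 1.5) val_data$x <- val_data$x / 255
  lr <- cfg$learning_rate
  best <- -Inf
  counter <- 0L
  vel <- list()
  best_params <- model$params
  best_epoch <- 0L
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_accuracy = numeric(0), lr = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(((cfg$seed %% 100003L) * 10007L + epoch) %% .Machine$integer.max)
    ord <- sample.int(n)
    losses <- numeric(0)
    for (idx in batch_indices(n, cfg$batch_size)) {
      bi <- ord[idx]
      fwd <- network_forward(model, train_data$x[, , , bi, drop = FALSE],
                             training = TRUE)
      model <- fwd$model
      ce <- softmax_xent(fwd$logits, train_data$y[bi])
      losses <- c(losses, ce$loss)
      grads <- network_backward(ce$dlogits, fwd$caches, model)
      grads$dx <- NULL
      if (is.finite(cfg$clip_grad_norm)) {
        gn <- grad_global_norm(grads)
        if (gn > cfg$clip_grad_norm)
          grads <- scale_grads(grads, cfg$clip_grad_norm / gn)
      }
      if (lr > 0) {
        upd <- update_params_rec(model$params, grads, vel, lr,
                                 cfg$momentum, cfg$weight_decay)
        model$params <- upd$params
        vel <- upd$vel
      }
    }
    val_acc <- model_accuracy(model, val_data, cfg$batch_size)
    if (val_acc > best) {
      best <- val_acc
      best_params <- model$params
      best_epoch <- epoch
      counter <- 0L
      if (!is.null(checkpoint_dir)) {
        if (!dir.exists(checkpoint_dir)) dir.create(checkpoint_dir, recursive = TRUE)
        save_checkpoint(model, file.path(checkpoint_dir, "best.rds"),
                        epoch = epoch, val_accuracy = val_acc)
      }
    } else {
      counter <- counter + 1L
      if (counter >= cfg$plateau_patience) {
        lr <- lr * cfg$lr_decay_factor
        counter <- 0L
      }
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(losses),
                                 val_accuracy = val_acc, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.4f  lr %.2g",
                      epoch, mean(losses), val_acc, lr))
  }
  if (!is.null(checkpoint_dir))
    utils::write.csv(log, file.path(checkpoint_dir, "train_log.csv"),
                     row.names = FALSE)
  best_model <- model
  best_model$params <- best_params
  list(model = best_model, log = log, best_epoch = best_epoch,
       best_val_accuracy = best, final_model = model)
}
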
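# Evaluation: confusion matrices and the usual multi-class indices.
#
# Per class k, with TP the diagonal entry, FP its column sum minus TP and FN
# its row sum minus TP:
#   P_k = TP / (TP + FP),  R_k = TP / (TP + FN)
# The headline precision/recall are macro averages (unweighted means over
# classes) and F1 = 2 P R / (P + R) is computed from them. Overall accuracy
# is trace/total; per-class accuracy is the per-class recall (diagonal over
# row sum). Mean inference time Ta = total time / image count, reported in
# ms per image.

#' Accumulate a confusion matrix
#'
#' @param true,predicted integer vectors of 0-based class labels.
#' @param n_classes number of classes K.
#' @return K x K integer matrix; rows are true classes, columns predicted.
#' @export
accumulate_confusion <- function(true, predicted, n_classes) {
  K <- as.integer(n_classes)
  stopifnot(length(true) == length(predicted))
  if (length(true) && (min(true, predicted) < 0 || max(true, predicted) >= K))
    stop(sprintf("labels must lie in [0, %d)", K))
  matrix(tabulate(true * K + predicted + 1L, nbins = K * K),
         K, K, byrow = TRUE,
         dimnames = list(true = 0:(K - 1), predicted = 0:(K - 1)))
}

#' F1 score from precision and recall
#'
#' `F1 = 2 P R / (P + R)` (0 when both are 0). Vectorized.
#'
#' @param precision,recall numeric in [0, 1].
#' @return numeric F1 values.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Compute the metrics report from a confusion matrix
#'
#' @param cm K x K confusion matrix (rows true, columns predicted).
#' @param total_time optional total inference time in seconds for the
#'   evaluated set.
#' @param n_images number of evaluated images (default `sum(cm)`).
#' @param average `"macro"` (unweighted mean over classes, default) or
#'   `"weighted"` (weighted by true-class frequency).
#' @return object of class `metrics_report`: list with `precision`,
#'   `recall`, `f1`, `accuracy`, `per_class_precision`, `per_class_recall`,
#'   `per_class_accuracy` (= per-class recall), `t_a_ms` (mean inference
#'   time, ms/image; NA when no timing given) and `confusion`.
#' @export
compute_metrics <- function(cm, total_time = NA_real_, n_images = sum(cm),
                            average = c("macro", "weighted")) {
  average <- match.arg(average)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix entries must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  col_tot <- colSums(cm)
  row_tot <- rowSums(cm)
  pk <- ifelse(col_tot > 0, tp / col_tot, 0)
  rk <- ifelse(row_tot > 0, tp / row_tot, 0)
  if (any(col_tot == 0))
    warning("some classes were never predicted; their precision is set to 0")
  if (any(row_tot == 0))
    warning("some classes have no true samples; their recall is set to 0")
  w <- if (average == "weighted") row_tot / total else rep(1 / nrow(cm), nrow(cm))
  P <- sum(w * pk)
  R <- sum(w * rk)
  structure(list(precision = P, recall = R, f1 = f1_score(P, R),
                 accuracy = sum(tp) / total,
                 per_class_precision = pk, per_class_recall = rk,
                 per_class_accuracy = rk,
                 t_a_ms = if (is.na(total_time)) NA_real_
                          else 1000 * total_time / n_images,
                 confusion = cm, average = average),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> (%s average)\n", x$average))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  accuracy %.2f%%\n",
              x$precision, x$recall, x$f1, 100 * x$accuracy))
  if (!is.na(x$t_a_ms))
    cat(sprintf("  mean inference time %.2f ms/image\n", x$t_a_ms))
  invisible(x)
}

#' Evaluate a model on a dataset
#'
#' Runs the forward pass in evaluation mode over the whole set, takes the
#' arg-max class per image, accumulates the confusion matrix and times the
#' loop.
#'
#' @param model a `pcsa_network`.
#' @param data list with `x` (`(H, W, 3, N)` array) and `y` (0-based
#'   labels); e.g. from [load_split()] or [as_image_batch()].
#' @param batch_size minibatch size for the forward passes.
#' @return list with `confusion` (K x K matrix) and `metrics` (a
#'   `metrics_report` including mean inference time).
#' @export
evaluate_model <- function(model, data, batch_size = 32L) {
  n <- length(data$y)
  if (n == 0L) stop("evaluation split is empty")
  if (max(data$x) > 1.5) data$x <- data$x / 255
  K <- model$spec$num_classes
  preds <- integer(n)
  t0 <- proc.time()[["elapsed"]]
  for (idx in batch_indices(n, batch_size)) {
    logits <- network_forward(model, data$x[, , , idx, drop = FALSE],
                              training = FALSE)$logits
    preds[idx] <- max.col(t(logits), ties.method = "first") - 1L
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  cm <- accumulate_confusion(data$y, preds, K)
  list(confusion = cm,
       metrics = compute_metrics(cm, total_time = elapsed, n_images = n))
}
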
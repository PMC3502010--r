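# SVM training, prediction, LOOCV and the accuracy/sensitivity/specificity
# report. Model fitting is delegated to e1071 (libsvm); this module owns the
# protocol: feature restriction, standardization contract, fold handling and
# metric conventions.

#' SVM configuration
#'
#' @param kernel `"rbf"` (radial basis) or `"linear"`.
#' @param cost Positive soft-margin cost `C`.
#' @param gamma RBF kernel width: a positive number, or `"scale"` for
#'   `1 / (n_features * var(x))` computed on the training matrix.
#' @param standardize Centre/scale features using training-set mean and SD
#'   (stored with the model and re-applied at prediction).
#' @param class_weights Optional named weights (`"-1"`, `"1"`) for
#'   imbalanced data; `NULL` (default) applies none.
#' @return List of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), cost = 1,
                       gamma = "scale", standardize = TRUE,
                       class_weights = NULL) {
  kernel <- match.arg(kernel)
  if (cost <= 0) stop("cost must be positive", call. = FALSE)
  if (!identical(gamma, "scale") && (!is.numeric(gamma) || gamma <= 0))
    stop("gamma must be positive or \"scale\"", call. = FALSE)
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 standardize = standardize, class_weights = class_weights),
            class = "svm_config")
}

#' Train a binary SVM on selected features
#'
#' Fits a support vector machine restricted to `active_features`. With
#' `standardize = TRUE` the training-set mean/SD are estimated and stored
#' with the model so prediction applies the identical affine map
#' (zero-variance columns are left unscaled).
#'
#' @param x Numeric matrix with named columns.
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param active_features Feature names to use (default: all columns).
#' @param config An [svm_config()].
#' @return A fitted model of class `node_svm`.
#' @export
train_svm <- function(x, y, active_features = colnames(x),
                      config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  if (is.null(active_features) || length(active_features) == 0)
    stop("active_features must be non-empty", call. = FALSE)
  if (!all(active_features %in% colnames(x)))
    stop("unknown feature(s) in active_features", call. = FALSE)
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("training data contains a single class", call. = FALSE)
  xs <- x[, active_features, drop = FALSE]
  scale_cols <- if (config$standardize)
    apply(xs, 2, function(col) stats::var(col) > 0) else
    rep(FALSE, ncol(xs))
  gamma <- config$gamma
  if (identical(gamma, "scale")) {
    # variance of the matrix the kernel actually sees (post-standardization)
    xk <- xs
    if (any(scale_cols)) xk[, scale_cols] <- scale(xs[, scale_cols])
    v <- stats::var(as.vector(xk))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(xs) * v) else 1 / ncol(xs)
  }
  fit <- e1071::svm(
    xs, factor(y, levels = c(-1, 1)),
    kernel = if (config$kernel == "rbf") "radial" else "linear",
    cost = config$cost, gamma = gamma, scale = scale_cols,
    class.weights = config$class_weights)
  structure(list(fit = fit, features = active_features, config = config),
            class = "node_svm")
}

#' Predict labels
#'
#' @param model A `node_svm` from [train_svm()].
#' @param x Numeric matrix containing at least the model's feature columns.
#' @return Numeric labels in `{-1, +1}` (length 0 for an empty matrix).
#' @export
predict_labels <- function(model, x) {
  stopifnot(inherits(model, "node_svm"))
  if (!all(model$features %in% colnames(x)))
    stop("x is missing model feature(s)", call. = FALSE)
  if (nrow(x) == 0) return(numeric(0))
  pred <- stats::predict(model$fit, x[, model$features, drop = FALSE])
  as.numeric(as.character(pred))
}

#' Confusion-table metrics
#'
#' Fills the accuracy/sensitivity/specificity report from predicted and
#' true labels. Positives are `+1` (malignant). A metric whose denominator
#' is empty (a class absent from `truth`) is reported as `NA`, never 0.
#'
#' @param predictions,truth Equal-length label vectors in `{-1, +1}`.
#' @return List of class `eval_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, and `confusion` (2x2 integer matrix: rows = truth
#'   -1/+1, columns = predicted -1/+1).
#' @export
evaluate <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1)
    stop("predictions and truth must have equal positive length",
         call. = FALSE)
  tp <- sum(truth == 1 & predictions == 1)
  fn <- sum(truth == 1 & predictions == -1)
  tn <- sum(truth == -1 & predictions == -1)
  fp <- sum(truth == -1 & predictions == 1)
  confusion <- matrix(as.integer(c(tn, fp, fn, tp)), 2, 2, byrow = TRUE,
                      dimnames = list(truth = c("-1", "1"),
                                      predicted = c("-1", "1")))
  structure(list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confusion = confusion), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f  sensitivity %s  specificity %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA",
                     sprintf("%.3f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA",
                     sprintf("%.3f", x$specificity))))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For each of the `n` samples, trains on the remaining `n - 1` and
#' predicts the held-out one; the `n` predictions are aggregated into one
#' confusion table. A fold whose training part degenerates to a single
#' class is counted as an error for that sample, with a warning.
#'
#' @param data A [labeled_data()] object with `n >= 3`, both classes
#'   present.
#' @param active_features Feature names to use (default: all).
#' @param config An [svm_config()].
#' @return An `eval_metrics` with attribute `n_fits` (number of train
#'   cycles performed).
#' @export
loocv <- function(data, active_features = colnames(data$x),
                  config = svm_config()) {
  stopifnot(inherits(data, "labeled_data"))
  n <- nrow(data$x)
  if (n < 3 || length(unique(data$y)) < 2)
    stop("LOOCV needs n >= 3 with both classes present", call. = FALSE)
  preds <- numeric(n)
  n_fits <- 0L
  for (i in seq_len(n)) {
    ytr <- data$y[-i]
    if (length(unique(ytr)) < 2) {
      warning("fold ", i, " has a single training class; counted as error")
      preds[i] <- -data$y[i]
      next
    }
    model <- train_svm(data$x[-i, , drop = FALSE], ytr, active_features,
                       config)
    n_fits <- n_fits + 1L
    preds[i] <- predict_labels(model, data$x[i, , drop = FALSE])
  }
  out <- evaluate(preds, data$y)
  attr(out, "n_fits") <- n_fits
  attr(out, "predictions") <- preds
  out
}
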
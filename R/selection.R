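# Backward-forward feature selection driven by permutation importance and a
# two-part stability loss. Labeled data travel as a list with `x` (numeric
# matrix, named columns) and `y` (labels in {-1, +1}); +1 denotes malignant.

#' Construct a labeled dataset
#'
#' @param x Numeric matrix, one row per sample, named feature columns.
#' @param y Labels in `{-1, +1}` (+1 = malignant, -1 = benign).
#' @return List of class `labeled_data` with elements `x` and `y`.
#' @export
labeled_data <- function(x, y) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("x must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("feat_", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1", call. = FALSE)
  structure(list(x = x, y = y), class = "labeled_data")
}

#' Stratified two-part split
#'
#' Splits a labeled dataset into two disjoint parts (training part `S1`,
#' evaluation part `S2`), stratified by class so both parts contain both
#' classes.
#'
#' @param data A [labeled_data()] object.
#' @param seed Integer seed controlling the assignment.
#' @param fraction Fraction of each class assigned to part 1.
#' @return List of class `split_data` with `part1` and `part2`
#'   (each a `labeled_data`).
#' @export
split_data <- function(data, seed = 1, fraction = 0.5) {
  stopifnot(inherits(data, "labeled_data"))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  idx1 <- with_seed(seed, {
    unlist(lapply(c(-1, 1), function(cl) {
      ids <- which(data$y == cl)
      if (length(ids) < 2)
        stop("each class needs >= 2 samples to split", call. = FALSE)
      sample(ids, max(1, round(fraction * length(ids))))
    }))
  })
  idx1 <- sort(idx1)
  idx2 <- setdiff(seq_along(data$y), idx1)
  structure(list(
    part1 = labeled_data(data$x[idx1, , drop = FALSE], data$y[idx1]),
    part2 = labeled_data(data$x[idx2, , drop = FALSE], data$y[idx2])),
    class = "split_data")
}

#' Overall accuracy
#'
#' Fraction of correctly predicted samples.
#'
#' @param predictions,truth Equal-length label vectors in `{-1, +1}`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_P <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1)
    stop("predictions and truth must have equal positive length",
         call. = FALSE)
  mean(predictions == truth)
}

#' Sensitivity (true-positive rate)
#'
#' `TP / (TP + FN)` with positives being label `+1` (malignant).
#'
#' @inheritParams accuracy_P
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_Q <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length", call. = FALSE)
  pos <- truth == 1
  if (!any(pos))
    stop("truth contains no positive samples; sensitivity undefined",
         call. = FALSE)
  mean(predictions[pos] == 1)
}

#' Two-part stability loss
#'
#' `|P(S1) - P(S2)| + 2 |Q(S1) - Q(S2)|` where `P` is accuracy and `Q`
#' sensitivity on the two data parts. Small values mean the classifier
#' behaves consistently across the split; the doubled sensitivity term
#' favours models whose detection of malignant nodes generalises.
#'
#' @param metrics1,metrics2 Numeric `(P, Q)` pairs, each entry in `[0, 1]`.
#' @return Loss in `[0, 3]`.
#' @export
selection_loss <- function(metrics1, metrics2) {
  m <- c(metrics1, metrics2)
  if (length(m) != 4 || any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("metrics must be two (P, Q) pairs with entries in [0, 1]",
         call. = FALSE)
  abs(metrics1[[1]] - metrics2[[1]]) + 2 * abs(metrics1[[2]] - metrics2[[2]])
}

# (P, Q) pair of a model on a labeled dataset.
model_metrics <- function(model, data) {
  pred <- predict_labels(model, data$x)
  c(P = accuracy_P(pred, data$y), Q = sensitivity_Q(pred, data$y))
}

# Loss of a feature subset: train on part1, compare (P, Q) on part1 vs part2.
subset_loss <- function(split, active, config) {
  model <- train_svm(split$part1$x, split$part1$y, active, config$svm)
  selection_loss(model_metrics(model, split$part1),
                 model_metrics(model, split$part2))
}

#' Permutation importance of one feature
#'
#' Importance of feature `feature` for a fitted model: the mean drop in
#' accuracy on the evaluation data when that feature's column is randomly
#' permuted, averaged over `n_repeats` permutations. Near zero for
#' irrelevant features, positive for features the model relies on.
#' Deterministic given `seed`. A constant column has importance 0 by
#' definition (permuting it cannot change anything) and raises a warning.
#'
#' @param model A fitted model from [train_svm()].
#' @param data Evaluation [labeled_data()] (the second part of the split).
#' @param feature Feature (column) name.
#' @param n_repeats Number of random permutations averaged.
#' @param seed Integer seed.
#' @param permute_fn Permutation generator `function(n)` returning an index
#'   vector; defaults to a uniform random permutation. Exposed for testing.
#' @return Mean accuracy drop (may be slightly negative by chance).
#' @export
permutation_importance <- function(model, data, feature, n_repeats = 20,
                                   seed = 1, permute_fn = NULL) {
  stopifnot(inherits(data, "labeled_data"))
  if (!feature %in% colnames(data$x))
    stop("unknown feature: ", feature, call. = FALSE)
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  col <- data$x[, feature]
  if (length(unique(col)) == 1) {
    warning("feature '", feature, "' is constant; importance defined as 0")
    return(0)
  }
  base_acc <- accuracy_P(predict_labels(model, data$x), data$y)
  gen <- if (is.null(permute_fn)) function(n) sample.int(n) else permute_fn
  with_seed(seed, {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- data$x
      xp[, feature] <- col[gen(length(col))]
      base_acc - accuracy_P(predict_labels(model, xp), data$y)
    }, numeric(1))
    mean(drops)
  })
}

#' Selection configuration
#'
#' @param min_features Floor on the retained feature count.
#' @param n_repeats Permutations averaged per importance estimate.
#' @param seed Integer seed for all selection randomness.
#' @param max_rounds Maximum backward/forward alternations in
#'   [select_features()].
#' @param svm An [svm_config()] used for every internal fit.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(min_features = 2, n_repeats = 20, seed = 1,
                             max_rounds = 10, svm = svm_config()) {
  if (min_features < 1) stop("min_features must be >= 1", call. = FALSE)
  structure(list(min_features = min_features, n_repeats = n_repeats,
                 seed = seed, max_rounds = max_rounds, svm = svm),
            class = "selection_config")
}

new_selection_state <- function(active, removed, importances, loss_history,
                                seed) {
  structure(list(active_features = active, removed_features = removed,
                 importances = importances, loss_history = loss_history,
                 rng_seed = seed),
            class = "selection_state")
}

#' Backward feature elimination
#'
#' Starting from all features, repeatedly trains on part 1, measures each
#' active feature's permutation importance on part 2, and removes the
#' least important one (ties broken by canonical column order). A removal
#' is committed only while the two-part stability loss does not exceed the
#' best value recorded so far; the first deteriorating removal is undone
#' and elimination stops. Never goes below `min_features`.
#'
#' @param split A [split_data()] object.
#' @param config A [selection_config()].
#' @param start Feature names to start from (default: all columns).
#' @return A `selection_state` with the surviving `active_features`, the
#'   `removed_features` in removal order, the last importance table and the
#'   loss history.
#' @export
backward_select <- function(split, config = selection_config(),
                            start = NULL) {
  stopifnot(inherits(split, "split_data"))
  canonical <- colnames(split$part1$x)
  if (is.null(start)) start <- canonical
  if (!all(start %in% canonical)) stop("unknown start features",
                                       call. = FALSE)
  if (length(start) < 2) stop("need >= 2 features", call. = FALSE)
  if (length(unique(split$part1$y)) < 2)
    stop("part1 contains a single class", call. = FALSE)
  active <- canonical[canonical %in% start]
  removed <- setdiff(canonical, active)
  best_loss <- subset_loss(split, active, config)
  loss_history <- best_loss
  importances <- NULL
  round <- 0L
  while (length(active) > config$min_features) {
    round <- round + 1L
    model <- train_svm(split$part1$x, split$part1$y, active, config$svm)
    part2 <- labeled_data(split$part2$x[, active, drop = FALSE],
                          split$part2$y)
    imps <- vapply(seq_along(active), function(j) {
      permutation_importance(model, part2, active[j],
                             n_repeats = config$n_repeats,
                             seed = config$seed + 131L * round + j)
    }, numeric(1))
    names(imps) <- active
    importances <- imps
    drop_feat <- active[which.min(imps)] # first minimum = canonical order
    trial <- setdiff(active, drop_feat)
    trial_loss <- subset_loss(split, trial, config)
    if (trial_loss > best_loss) break
    active <- trial
    removed <- c(removed, drop_feat)
    best_loss <- min(best_loss, trial_loss)
    loss_history <- c(loss_history, trial_loss)
  }
  new_selection_state(active, removed, importances, loss_history,
                      config$seed)
}

#' Forward feature re-addition
#'
#' Greedy complement of [backward_select()]: scans the removed features
#' and re-adds, one at a time, the candidate that most increases accuracy
#' on part 2 (ties broken by canonical order), stopping at the first scan
#' where no candidate strictly improves it.
#'
#' @param split A [split_data()] object.
#' @param state A `selection_state`, normally from [backward_select()].
#' @param config A [selection_config()].
#' @return An updated `selection_state`.
#' @export
forward_select <- function(split, state, config = selection_config()) {
  stopifnot(inherits(split, "split_data"),
            inherits(state, "selection_state"))
  canonical <- colnames(split$part1$x)
  active <- state$active_features
  pool <- state$removed_features
  loss_history <- state$loss_history
  part2_acc <- function(feats) {
    model <- train_svm(split$part1$x, split$part1$y, feats, config$svm)
    accuracy_P(predict_labels(model, split$part2$x), split$part2$y)
  }
  base_acc <- part2_acc(active)
  while (length(pool) > 0) {
    pool <- canonical[canonical %in% pool] # canonical order
    accs <- vapply(pool, function(f) part2_acc(c(active, f)), numeric(1))
    if (max(accs) <= base_acc) break
    add <- pool[which.max(accs)] # first maximum = canonical tie-break
    active <- canonical[canonical %in% c(active, add)]
    pool <- setdiff(pool, add)
    base_acc <- max(accs)
    loss_history <- c(loss_history, subset_loss(split, active, config))
  }
  new_selection_state(active, setdiff(state$removed_features, active),
                      state$importances, loss_history, state$rng_seed)
}

#' Backward-forward feature selection
#'
#' Alternates [backward_select()] and [forward_select()] until the active
#' feature set is unchanged between consecutive rounds (or `max_rounds` is
#' reached), returning the state after the final forward pass.
#'
#' @param data A [labeled_data()] object (split internally), or an existing
#'   [split_data()].
#' @param config A [selection_config()].
#' @return The final `selection_state`.
#' @export
select_features <- function(data, config = selection_config()) {
  split <- if (inherits(data, "split_data")) data else
    split_data(data, seed = config$seed)
  prev <- NULL
  state <- NULL
  for (round in seq_len(config$max_rounds)) {
    back_cfg <- config
    back_cfg$seed <- config$seed + 7919L * round
    start <- if (is.null(state)) NULL else state$active_features
    state <- backward_select(split, back_cfg, start = start)
    # candidate pool for the forward pass: everything not currently active
    state$removed_features <-
      setdiff(colnames(split$part1$x), state$active_features)
    state <- forward_select(split, state, back_cfg)
    if (!is.null(prev) && setequal(prev, state$active_features)) break
    prev <- state$active_features
  }
  state$rng_seed <- config$seed
  state
}
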
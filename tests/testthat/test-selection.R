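# Metrics, the two-part stability loss, permutation importance, and the
# backward/forward selection loops.

test_that("accuracy and sensitivity follow their counting definitions", {
  truth <- c(rep(1, 5), rep(-1, 5))
  pred <- truth; pred[c(1, 10)] <- -pred[c(1, 10)]
  expect_equal(accuracy_P(pred, truth), 0.8)
  expect_equal(accuracy_P(truth, truth), 1)
  expect_equal(accuracy_P(-truth, truth), 0)
  # TP = 9, FN = 1
  t2 <- c(rep(1, 10), rep(-1, 4))
  p2 <- t2; p2[1] <- -1
  expect_equal(sensitivity_Q(p2, t2), 0.9)
  expect_equal(sensitivity_Q(t2, t2), 1)
  p3 <- t2; p3[t2 == 1] <- -1
  expect_equal(sensitivity_Q(p3, t2), 0)
  expect_error(sensitivity_Q(c(1, -1), c(-1, -1)), "no positive")
})

test_that("the stability loss is |dP| + 2|dQ|, symmetric, zero iff equal", {
  expect_equal(selection_loss(c(0.9, 0.8), c(0.9, 0.8)), 0)
  expect_equal(selection_loss(c(0.8, 0.9), c(0.7, 0.85)), 0.2,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(2); b <- runif(2)
    expect_equal(selection_loss(a, b), selection_loss(b, a))
    expect_gte(selection_loss(a, b), 0)
    expect_lte(selection_loss(a, b), 3)
  }
  expect_error(selection_loss(c(1.2, 0.5), c(0.5, 0.5)), "0, 1")
})

test_that("permutation importance separates informative from noise features", {
  d <- make_feature_dataset(table_spec(n_samples = 200, informative = 1,
                                       effect_size = 3, seed = 5))
  sp <- split_data(d, seed = 2)
  model <- train_svm(sp$part1$x, sp$part1$y)
  # identity permutation hook gives exactly zero
  expect_identical(
    permutation_importance(model, sp$part2, "f01", n_repeats = 3, seed = 1,
                           permute_fn = function(n) seq_len(n)), 0)
  imp_inf <- permutation_importance(model, sp$part2, "f01",
                                    n_repeats = 20, seed = 7)
  imp_noise <- permutation_importance(model, sp$part2, "f07",
                                      n_repeats = 20, seed = 7)
  expect_gt(imp_inf, 0.3)
  expect_lt(abs(imp_noise), 0.05)
  # deterministic given seed
  expect_identical(imp_inf,
                   permutation_importance(model, sp$part2, "f01",
                                          n_repeats = 20, seed = 7))
  # constant column: importance 0 with warning
  x <- sp$part2$x; x[, "f03"] <- 2
  d2 <- labeled_data(x, sp$part2$y)
  expect_warning(imp0 <- permutation_importance(model, d2, "f03"),
                 "constant")
  expect_identical(imp0, 0)
})

test_that("backward selection keeps strongly informative features and respects the floor", {
  d <- make_feature_dataset(table_spec(n_samples = 200, informative = 1:3,
                                       effect_size = 2, seed = 101))
  sp <- split_data(d, seed = 1)
  st <- backward_select(sp, selection_config(seed = 1))
  expect_true(all(c("f01", "f02", "f03") %in% st$active_features))
  expect_gte(length(st$active_features), 2)
  # identical runs give identical sets
  st2 <- backward_select(sp, selection_config(seed = 1))
  expect_identical(st$active_features, st2$active_features)
  # two-feature dataset at the floor: nothing removed
  d2 <- make_feature_dataset(table_spec(n_samples = 50, n_features = 2,
                                        informative = 1, effect_size = 2,
                                        seed = 4))
  sp2 <- split_data(d2, seed = 1)
  st3 <- backward_select(sp2, selection_config(min_features = 2, seed = 1))
  expect_setequal(st3$active_features, c("f01", "f02"))
})

test_that("forward selection re-adds a wrongly dropped informative feature and stops otherwise", {
  d <- make_feature_dataset(table_spec(n_samples = 200, informative = 1:2,
                                       effect_size = 2.5, seed = 11))
  sp <- split_data(d, seed = 3)
  cfg <- selection_config(seed = 2)
  # hostile state: informative f01 sits in the removed pool
  hostile <- structure(list(
    active_features = c("f02", "f05"),
    removed_features = c("f01", "f04"),
    importances = NULL, loss_history = numeric(0), rng_seed = 2),
    class = "selection_state")
  st <- forward_select(sp, hostile, cfg)
  expect_true("f01" %in% st$active_features)
  # empty pool: state unchanged
  none <- structure(list(
    active_features = c("f01", "f02"), removed_features = character(0),
    importances = NULL, loss_history = numeric(0), rng_seed = 2),
    class = "selection_state")
  expect_identical(forward_select(sp, none, cfg)$active_features,
                   c("f01", "f02"))
})

test_that("full backward-forward selection is reproducible and bounded", {
  d <- make_feature_dataset(table_spec(n_samples = 120, informative = 1:3,
                                       effect_size = 2, seed = 33))
  cfg <- selection_config(seed = 5)
  a <- select_features(d, cfg)
  b <- select_features(d, cfg)
  expect_identical(a$active_features, b$active_features)
  expect_gte(length(a$active_features), cfg$min_features)
  expect_lte(length(a$active_features), 19)
  expect_true(all(c("f01", "f02", "f03") %in% a$active_features))
})

test_that("stratified split is disjoint, class-complete and seeded", {
  d <- make_feature_dataset(table_spec(n_samples = 60, seed = 8,
                                       class_balance = 0.3))
  sp <- split_data(d, seed = 4)
  n1 <- nrow(sp$part1$x); n2 <- nrow(sp$part2$x)
  expect_equal(n1 + n2, 60)
  expect_setequal(unique(sp$part1$y), c(-1, 1))
  expect_setequal(unique(sp$part2$y), c(-1, 1))
  sp2 <- split_data(d, seed = 4)
  expect_identical(sp$part1$x, sp2$part1$x)
})
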
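test_that("undersampling balances to the minority class deterministically", {
  df <- noise_classif_data(n_per_class = 100)
  df <- df[c(1:100, 101:150, 201:275), ] # counts 100 / 50 / 75
  bal <- balance_classes(df, seed = 1)
  expect_equal(as.integer(table(bal$excursion_label)), rep(50L, 3))
  # already balanced: sizes unchanged
  bal2 <- balance_classes(bal, seed = 2)
  expect_equal(as.integer(table(bal2$excursion_label)), rep(50L, 3))
  # same sizes but generally different membership across seeds
  a <- balance_classes(df, seed = 1)
  b <- balance_classes(df, seed = 99)
  expect_equal(dim(a), dim(b))
  expect_false(identical(a, b))
  expect_identical(balance_classes(df, seed = 1), a)
  # absent class is an explicit error naming it
  expect_error(balance_classes(df[df$excursion_label != "PersLow", ]), "PersLow")
})

test_that("classification metrics satisfy their defining identities", {
  # hand-built confusion: truth/pred vectors with known 3x3 table
  lv <- glucowear:::excursion_levels()
  truth <- factor(rep(lv, times = c(10, 20, 15)), levels = lv)
  pred <- factor(c(rep(lv[1], 7), rep(lv[2], 2), lv[3],
                   rep(lv[1], 3), rep(lv[2], 16), lv[3],
                   rep(lv[1], 2), rep(lv[2], 2), rep(lv[3], 11)), levels = lv)
  m <- classification_metrics(truth, pred)
  cm <- m$confusion
  expect_equal(unname(rowSums(cm)), c(10, 20, 15))
  # balanced accuracy = unweighted mean of per-class recalls
  expect_equal(m$balanced_accuracy, mean(diag(cm) / rowSums(cm)))
  # per-class accuracy = diagonal over row sums
  expect_equal(unname(m$per_class_accuracy), unname(diag(cm) / rowSums(cm)))
  # weighted recall recomputed from the stored confusion matrix
  w <- rowSums(cm) / sum(cm)
  expect_equal(m$weighted_recall, sum(w * diag(cm) / rowSums(cm)))
  expect_equal(m$weighted_precision, sum(w * diag(cm) / colSums(cm)))
  expect_true(m$r2 >= 0)
  # perfect prediction
  perf <- classification_metrics(truth, truth)
  expect_equal(perf$balanced_accuracy, 1)
  expect_equal(perf$r2, 1)
})

test_that("recursive elimination keeps planted signal features", {
  # k = total features: identity subset
  df <- noise_classif_data(n_per_class = 30)
  x <- df[, feature_schema()]
  y <- df$excursion_label
  expect_setequal(rfe_select(x, y, k = 69), feature_schema())

  # label is a function of one feature; everything else pure noise
  set.seed(21)
  strong <- noise_classif_data(n_per_class = 60)
  strong$hr_mean <- as.integer(strong$excursion_label) + rnorm(180, 0, 0.05)
  sel <- rfe_select(strong[, feature_schema()], strong$excursion_label, k = 5)
  expect_true("hr_mean" %in% sel)

  # k = 1 on a 3-feature separable toy: the separating feature survives
  set.seed(22)
  toy_x <- matrix(rnorm(300), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "sep")))
  toy_y <- factor(rep(glucowear:::excursion_levels(), length.out = 100),
                  levels = glucowear:::excursion_levels())
  toy_x[, "sep"] <- as.integer(toy_y) * 10 + rnorm(100, 0, 0.1)
  expect_equal(rfe_select(toy_x, toy_y, k = 1), "sep")

  expect_error(rfe_select(toy_x, toy_y, k = 4), "exceeds")
})

test_that("stratified folds cover all rows and keep every class per fold", {
  y <- factor(rep(glucowear:::excursion_levels(), times = c(40, 40, 40)),
              levels = glucowear:::excursion_levels())
  folds <- glucowear:::stratified_folds(y, k = 10, times = 3, seed = 0)
  expect_length(folds, 30)
  for (r in 1:3) {
    idx <- sort(unlist(folds[(10 * (r - 1) + 1):(10 * r)]))
    expect_equal(idx, seq_along(y)) # each repeat partitions the data
  }
  for (f in folds) {
    expect_setequal(as.character(unique(y[f])), glucowear:::excursion_levels())
  }
})

test_that("cross-validation is deterministic and near-perfect on separable data", {
  df <- separable_classif_data(n_per_class = 40)
  cfg <- classifier_config(n_splits = 3, n_repeats = 1, seed = 0, rfe_k = 5)
  rep1 <- run_cv(df, cfg)
  expect_equal(nrow(rep1$fold_metrics), 3)
  ba <- glance(rep1)$balanced_accuracy_mean
  expect_gte(ba, 0.95)
  rep2 <- run_cv(df, cfg)
  expect_identical(rep1$fold_metrics, rep2$fold_metrics)
  expect_identical(rep1$confusion, rep2$confusion)
  # confusion matrix accumulates one prediction per row per repeat
  expect_equal(sum(rep1$confusion), nrow(df))
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_s3_class(autoplot(rep1), "ggplot")
})

test_that("the holdout split reports both models with per-class accuracies", {
  df <- separable_classif_data(n_per_class = 40)
  cfg <- classifier_config(seed = 3, rfe_k = 5)
  h1 <- run_holdout(df, cfg)
  h2 <- run_holdout(df, cfg)
  expect_identical(glance(h1), glance(h2))
  expect_named(h1$decision_tree$per_class_accuracy)
  cm <- h1$decision_tree$confusion
  expect_equal(unname(h1$decision_tree$per_class_accuracy),
               unname(diag(cm) / rowSums(cm)))
  expect_gte(h1$decision_tree$metrics$balanced_accuracy, 0.9)
  # the separable feature is linearly separating, so logistic succeeds too
  expect_gte(h1$logistic$metrics$balanced_accuracy, 0.9)
  expect_equal(nrow(tidy(h1)), 10)
})

test_that("every elimination estimator runs and ranks a planted feature first", {
  set.seed(31)
  df <- noise_classif_data(n_per_class = 25)
  df$sugar_2h <- as.integer(df$excursion_label) * 3 + rnorm(75, 0, 0.05)
  x <- as.matrix(df[, feature_schema()])[, 1:12]
  x[, "hr_q3"] <- df$sugar_2h # plant inside the small subset
  y <- df$excursion_label
  for (est in c("decision_tree", "logistic", "perceptron",
                "random_forest", "gradient_boosting")) {
    sel <- rfe_select(x, y, k = 3, estimator = est, seed = 1)
    expect_true("hr_q3" %in% sel, info = est)
  }
})
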
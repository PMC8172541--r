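#' Classifier configuration
#'
#' Settings for multiclass excursion classification: repeated stratified
#' k-fold cross-validation (10 splits, 3 repeats), per-fold recursive
#' feature elimination down to 20 features with a decision-tree estimator,
#' and a decision-tree final model — the configuration the source analysis
#' found best, with a multinomial logistic baseline available. Decision-tree
#' hyperparameters are not pinned by the method, so they are exposed here.
#'
#' @param n_splits Folds per repeat (>= 2).
#' @param n_repeats Repeats of the k-fold scheme.
#' @param seed RNG seed for fold assignment and estimator fits.
#' @param rfe_k Number of features kept by recursive elimination (<= 69).
#' @param rfe_estimator Estimator ranking features inside the elimination:
#'   `"decision_tree"`, `"logistic"`, `"perceptron"`, `"random_forest"` or
#'   `"gradient_boosting"`.
#' @param final_model Classifier fit on the selected features:
#'   `"decision_tree"` or `"logistic"`.
#' @param tree_control [rpart::rpart.control()] list for tree fits.
#' @param holdout_train_fraction Train share of the single stratified split
#'   used by [run_holdout()].
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(n_splits = 10, n_repeats = 3, seed = 0,
                              rfe_k = 20,
                              rfe_estimator = c("decision_tree", "logistic",
                                                "perceptron", "random_forest",
                                                "gradient_boosting"),
                              final_model = c("decision_tree", "logistic"),
                              tree_control = rpart::rpart.control(
                                cp = 0.001, minsplit = 5, xval = 0, maxdepth = 30),
                              holdout_train_fraction = 0.7) {
  if (n_splits < 2) abort("n_splits must be >= 2")
  if (rfe_k > length(feature_schema())) abort("rfe_k cannot exceed 69")
  structure(list(
    n_splits = n_splits, n_repeats = n_repeats, seed = seed, rfe_k = rfe_k,
    rfe_estimator = match.arg(rfe_estimator),
    final_model = match.arg(final_model),
    tree_control = tree_control,
    holdout_train_fraction = holdout_train_fraction
  ), class = "classifier_config")
}

#' Balance classes by random undersampling
#'
#' Undersamples every class to the minority-class count, without
#' replacement. Deterministic given `seed`.
#'
#' @param data Tibble with an `excursion_label` factor column.
#' @param seed RNG seed.
#' @return The balanced tibble (row order: class blocks in level order).
#' @export
balance_classes <- function(data, seed = 0) {
  check_columns(data, "excursion_label", "classification data")
  y <- data$excursion_label
  counts <- table(factor(y, levels = excursion_levels()))
  absent <- names(counts)[counts == 0]
  if (length(absent)) {
    abort(sprintf("class absent from data: %s", paste(absent, collapse = ", ")))
  }
  n_min <- min(counts)
  set.seed(seed)
  keep <- unlist(lapply(excursion_levels(), function(cls) {
    idx <- which(y == cls)
    sort(sample(idx, n_min))
  }))
  data[keep, ]
}

# ---- estimators ------------------------------------------------------------

fit_clf <- function(x, y, estimator, seed, tree_control) {
  set.seed(seed)
  switch(estimator,
    decision_tree = {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = tree_control)
      structure(list(fit = fit, features = colnames(x)), class = "gw_tree")
    },
    logistic = {
      ctr <- colMeans(x)
      scl <- apply(x, 2, sd)
      scl[scl == 0] <- 1
      xs <- scale(x, ctr, scl)
      df <- data.frame(xs, check.names = FALSE)
      df$.y <- y
      fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                            maxit = 200, MaxNWts = 5000)
      structure(list(fit = fit, features = colnames(x), center = ctr, scale = scl),
                class = "gw_logistic")
    },
    random_forest = {
      fit <- ranger::ranger(x = x, y = y, num.trees = 100,
                            importance = "impurity", seed = seed,
                            num.threads = 1)
      structure(list(fit = fit, features = colnames(x)), class = "gw_rf")
    },
    gradient_boosting = {
      yi <- as.integer(y) - 1L
      fit <- xgboost::xgb.train(
        params = list(max_depth = 6, eta = 0.1, objective = "multi:softmax",
                      num_class = 3, nthread = 1, seed = seed),
        data = xgboost::xgb.DMatrix(as.matrix(x), label = yi, nthread = 1),
        nrounds = 50, verbose = 0
      )
      structure(list(fit = fit, features = colnames(x), levels = levels(y)),
                class = "gw_xgb_clf")
    },
    perceptron = fit_perceptron(x, y, seed),
    abort(sprintf("unknown estimator: %s", estimator))
  )
}

predict_clf <- function(model, x) {
  x <- x[, model$features, drop = FALSE]
  switch(class(model)[1],
    gw_tree = {
      p <- predict(model$fit, data.frame(x, check.names = FALSE), type = "class")
      factor(as.character(p), levels = excursion_levels())
    },
    gw_logistic = {
      xs <- scale(x, model$center, model$scale)
      p <- predict(model$fit, data.frame(xs, check.names = FALSE))
      factor(as.character(p), levels = excursion_levels())
    },
    gw_rf = {
      p <- predict(model$fit, data = x, num.threads = 1)$predictions
      factor(as.character(p), levels = excursion_levels())
    },
    gw_xgb_clf = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))
      factor(model$levels[p + 1L], levels = excursion_levels())
    },
    gw_perceptron = predict_perceptron(model, x),
    abort("unknown model class")
  )
}

clf_importance <- function(model) {
  feats <- model$features
  imp <- setNames(rep(0, length(feats)), feats)
  switch(class(model)[1],
    gw_tree = {
      vi <- model$fit$variable.importance
      imp[names(vi)[names(vi) %in% feats]] <- vi[names(vi) %in% feats]
    },
    gw_logistic = {
      co <- stats::coef(model$fit)
      if (is.null(dim(co))) co <- matrix(co, nrow = 1, dimnames = list(NULL, names(co)))
      for (f in feats) {
        if (f %in% colnames(co)) imp[f] <- sum(abs(co[, f]))
      }
    },
    gw_rf = {
      vi <- model$fit$variable.importance
      imp[names(vi)] <- vi
    },
    gw_xgb_clf = {
      m <- xgboost::xgb.importance(feature_names = feats, model = model$fit)
      imp[m$Feature] <- m$Gain
    },
    gw_perceptron = {
      imp[] <- colSums(abs(model$weights))
    }
  )
  imp
}

# One-vs-rest averaged perceptron on standardized inputs; kept minimal, it
# exists only to complete the elimination-estimator menu.
fit_perceptron <- function(x, y, seed, epochs = 10) {
  set.seed(seed)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  classes <- levels(y)
  W <- matrix(0, nrow = length(classes), ncol = ncol(x),
              dimnames = list(classes, colnames(x)))
  b <- setNames(rep(0, length(classes)), classes)
  Wa <- W; ba <- b
  n <- nrow(xs)
  for (cls_i in seq_along(classes)) {
    t_y <- ifelse(y == classes[cls_i], 1, -1)
    w <- rep(0, ncol(xs)); b0 <- 0
    wsum <- w; bsum <- 0; steps <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        pred <- sum(w * xs[i, ]) + b0
        if (t_y[i] * pred <= 0) {
          w <- w + t_y[i] * xs[i, ]
          b0 <- b0 + t_y[i]
        }
        wsum <- wsum + w; bsum <- bsum + b0; steps <- steps + 1
      }
    }
    Wa[cls_i, ] <- wsum / steps
    ba[cls_i] <- bsum / steps
  }
  structure(list(weights = Wa, bias = ba, center = ctr, scale = scl,
                 features = colnames(x), levels = classes),
            class = "gw_perceptron")
}

predict_perceptron <- function(model, x) {
  xs <- scale(as.matrix(x), model$center, model$scale)
  scores <- xs %*% t(model$weights)
  scores <- sweep(scores, 2, model$bias, `+`)
  factor(model$levels[max.col(scores, ties.method = "first")],
         levels = excursion_levels())
}

#' Recursive feature elimination
#'
#' Repeatedly fits the estimator on the remaining features and drops the
#' least important one (tree/forest impurity importance, boosting gain, or
#' summed absolute coefficients for linear estimators; ties drop the
#' later column) until `k` features remain. Must only ever see training
#' rows — it is called inside each cross-validation fold.
#'
#' @param x Numeric feature matrix or tibble (training rows only).
#' @param y Factor of class labels.
#' @param k Number of features to retain.
#' @param estimator Estimator name, see [classifier_config()].
#' @param seed RNG seed.
#' @param tree_control Control list for tree fits.
#' @return Character vector of `k` retained feature names, in original
#'   column order.
#' @export
rfe_select <- function(x, y, k, estimator = "decision_tree", seed = 0,
                       tree_control = rpart::rpart.control(
                         cp = 0.001, minsplit = 5, xval = 0, maxdepth = 30)) {
  x <- as.matrix(x)
  if (k > ncol(x)) abort("k exceeds the number of available features")
  remaining <- colnames(x)
  while (length(remaining) > k) {
    model <- fit_clf(x[, remaining, drop = FALSE], y, estimator,
                     seed = seed, tree_control = tree_control)
    imp <- clf_importance(model)[remaining]
    worst <- which(imp == min(imp))
    drop_f <- remaining[worst[length(worst)]]
    remaining <- setdiff(remaining, drop_f)
  }
  remaining
}

# ---- folds and metrics -----------------------------------------------------

# Stratified k-fold assignment repeated `times` times; returns a list of
# integer test-index vectors, length k * times.
stratified_folds <- function(y, k, times, seed) {
  set.seed(seed)
  folds <- list()
  for (r in seq_len(times)) {
    assign <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(k), length(idx))
    }
    for (f in seq_len(k)) {
      folds[[length(folds) + 1L]] <- which(assign == f)
    }
  }
  folds
}

#' Classification metrics from truth and prediction
#'
#' Balanced accuracy (unweighted mean of per-class recalls), support-weighted
#' precision, recall and F1, the coefficient of determination on
#' integer-coded labels (PersLow = 0, PersNorm = 1, PersHigh = 2) floored at
#' zero, the 3x3 confusion matrix (rows = truth) and per-class accuracies
#' (confusion diagonal over row sums).
#'
#' @param truth,pred Factors with the excursion levels.
#' @return Named list of scalars plus `confusion` and `per_class_accuracy`.
#' @export
classification_metrics <- function(truth, pred) {
  lv <- excursion_levels()
  truth <- factor(truth, levels = lv)
  pred <- factor(pred, levels = lv)
  cm <- table(truth = truth, pred = pred)
  support <- rowSums(cm)
  recall <- ifelse(support > 0, diag(cm) / support, 0)
  pred_n <- colSums(cm)
  precision <- ifelse(pred_n > 0, diag(cm) / pred_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  wts <- support / sum(support)
  yi <- as.integer(truth) - 1L
  pi <- as.integer(pred) - 1L
  ss_tot <- sum((yi - mean(yi))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - sum((yi - pi)^2) / ss_tot) else 0
  list(
    balanced_accuracy = mean(recall[support > 0]),
    weighted_precision = sum(wts * precision),
    weighted_recall = sum(wts * recall),
    weighted_f1 = sum(wts * f1),
    r2 = r2,
    confusion = cm,
    per_class_accuracy = recall
  )
}

#' Repeated stratified cross-validated excursion classification
#'
#' Runs the full scheme on a (pre-balanced) feature table: for each of the
#' `n_splits * n_repeats` stratified folds, recursive feature elimination
#' selects `rfe_k` features on the training rows only, the final model is
#' fit on those rows, and metrics are taken on the held-out fold. No
#' test-fold information reaches selection or fitting.
#'
#' @param data Tibble with the 69 feature columns and `excursion_label`.
#' @param config A [classifier_config()].
#' @return Object of class `cv_report`: per-fold metrics, their mean/sd
#'   summary, the summed confusion matrix and the configuration. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_cv <- function(data, config = classifier_config()) {
  xy <- classification_xy(data)
  folds <- stratified_folds(xy$y, config$n_splits, config$n_repeats, config$seed)
  fold_rows <- vector("list", length(folds))
  confusion <- matrix(0, 3, 3, dimnames = list(excursion_levels(), excursion_levels()))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(xy$y), test_idx)
    y_tr <- xy$y[train_idx]
    if (nlevels(droplevels(y_tr)) < 3 ||
        nlevels(droplevels(xy$y[test_idx])) < 3) {
      abort(sprintf("stratification error: fold %d is missing a class", f))
    }
    sel <- rfe_select(xy$x[train_idx, , drop = FALSE], y_tr, config$rfe_k,
                      estimator = config$rfe_estimator,
                      seed = config$seed + f,
                      tree_control = config$tree_control)
    model <- fit_clf(xy$x[train_idx, sel, drop = FALSE], y_tr,
                     config$final_model, seed = config$seed + f,
                     tree_control = config$tree_control)
    pred <- predict_clf(model, xy$x[test_idx, , drop = FALSE])
    m <- classification_metrics(xy$y[test_idx], pred)
    confusion <- confusion + unclass(m$confusion)
    fold_rows[[f]] <- tibble::tibble(
      fold = f, balanced_accuracy = m$balanced_accuracy,
      weighted_precision = m$weighted_precision,
      weighted_recall = m$weighted_recall,
      weighted_f1 = m$weighted_f1, r2 = m$r2
    )
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  structure(list(
    fold_metrics = fold_metrics,
    summary = summarize_folds(fold_metrics),
    confusion = confusion,
    config = config
  ), class = "cv_report")
}

classification_xy <- function(data) {
  check_columns(data, c(feature_schema(), "excursion_label"), "classification data")
  y <- factor(as.character(data$excursion_label), levels = excursion_levels())
  if (anyNA(y)) abort("excursion_label contains missing values")
  x <- as.matrix(data[, feature_schema()])
  if (anyNA(x)) abort("feature matrix contains missing values; impute first")
  list(x = x, y = y)
}

summarize_folds <- function(fold_metrics) {
  long <- tidyr::pivot_longer(fold_metrics, -"fold",
                              names_to = "metric", values_to = "value")
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value), sd = sd(.data$value),
                   .groups = "drop")
}

#' Single stratified 70/30 holdout classification
#'
#' Fits both the decision-tree model and the multinomial-logistic baseline
#' on one stratified train/test split (feature elimination on the training
#' rows only, exactly as inside cross-validation) and reports metrics,
#' confusion matrix and per-class accuracies for each.
#'
#' @param data Tibble with the 69 feature columns and `excursion_label`.
#' @param config A [classifier_config()].
#' @return Object of class `holdout_report` with elements `decision_tree`
#'   and `logistic`, each carrying `metrics`, `confusion` and
#'   `per_class_accuracy`.
#' @export
run_holdout <- function(data, config = classifier_config()) {
  xy <- classification_xy(data)
  set.seed(config$seed)
  test_idx <- unlist(lapply(levels(xy$y), function(cls) {
    idx <- sample(which(xy$y == cls))
    n_test <- max(1L, round((1 - config$holdout_train_fraction) * length(idx)))
    idx[seq_len(n_test)]
  }))
  train_idx <- setdiff(seq_along(xy$y), test_idx)
  y_tr <- xy$y[train_idx]
  sel <- rfe_select(xy$x[train_idx, , drop = FALSE], y_tr, config$rfe_k,
                    estimator = config$rfe_estimator, seed = config$seed,
                    tree_control = config$tree_control)
  one <- function(model_kind) {
    model <- fit_clf(xy$x[train_idx, sel, drop = FALSE], y_tr, model_kind,
                     seed = config$seed, tree_control = config$tree_control)
    pred <- predict_clf(model, xy$x[test_idx, , drop = FALSE])
    m <- classification_metrics(xy$y[test_idx], pred)
    list(metrics = m[c("balanced_accuracy", "weighted_precision",
                       "weighted_recall", "weighted_f1", "r2")],
         confusion = m$confusion,
         per_class_accuracy = m$per_class_accuracy)
  }
  structure(list(decision_tree = one("decision_tree"),
                 logistic = one("logistic"),
                 selected_features = sel,
                 config = config),
            class = "holdout_report")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  ba <- s[s$metric == "balanced_accuracy", ]
  cat(sprintf("<cv_report> %d folds | balanced accuracy %.3f +/- %.3f\n",
              nrow(x$fold_metrics), ba$mean, ba$sd))
  invisible(x)
}

#' @rdname run_cv
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$fold_metrics

#' @rdname run_cv
#' @export
glance.cv_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"), names_glue = "{metric}_{.value}")
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf(
    "<holdout_report> tree balanced accuracy %.3f | logistic %.3f\n",
    x$decision_tree$metrics$balanced_accuracy,
    x$logistic$metrics$balanced_accuracy
  ))
  invisible(x)
}

#' @rdname run_holdout
#' @param x A `holdout_report`.
#' @param ... Unused.
#' @export
tidy.holdout_report <- function(x, ...) {
  purrr::map_dfr(c("decision_tree", "logistic"), function(mod) {
    m <- x[[mod]]$metrics
    tibble::tibble(model = mod, metric = names(m), value = unlist(m))
  })
}

#' @rdname run_holdout
#' @export
glance.holdout_report <- function(x, ...) {
  purrr::map_dfr(c("decision_tree", "logistic"), function(mod) {
    m <- x[[mod]]$metrics
    dplyr::bind_cols(tibble::tibble(model = mod), tibble::as_tibble(m))
  })
}
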
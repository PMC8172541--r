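#' Regressor configuration
#'
#' Gradient-boosted tree hyperparameters (maximum depth 6, 100 estimators,
#' learning rate 0.1 — the tuned values the analysis pins), the random-forest
#' feature-selection settings (1000 trees, normalized impurity-importance
#' cutoff 0.005), and the RNG seed. Forest and booster seeds for fold `f`
#' are derived as `seed + f`.
#'
#' @param gbt List: `max_depth`, `n_estimators`, `learning_rate`.
#' @param fs List: `rf_trees`, `importance_cutoff` (on importances
#'   normalized to sum to 1).
#' @param seed Base RNG seed.
#' @param clip Optional length-2 numeric; when set, predictions are clipped
#'   to this mg/dL range (off by default).
#' @return List of class `regressor_config`.
#' @export
regressor_config <- function(gbt = list(max_depth = 6, n_estimators = 100,
                                        learning_rate = 0.1),
                             fs = list(rf_trees = 1000,
                                       importance_cutoff = 0.005),
                             seed = 0, clip = NULL) {
  if (fs$importance_cutoff < 0 || fs$importance_cutoff > 1) {
    abort("importance_cutoff must be in [0, 1]")
  }
  if (fs$rf_trees < 1) abort("rf_trees must be >= 1")
  structure(list(gbt = gbt, fs = fs, seed = seed, clip = clip),
            class = "regressor_config")
}

#' Regression error metrics
#'
#' `rmse()` is the root mean squared error in mg/dL, `mape()` the mean
#' absolute percent error (`100 * mean(|y - yhat| / y)`), and accuracy is
#' defined as `100 - MAPE`.
#'
#' @param y Observed glucose (must be positive for MAPE).
#' @param yhat Predictions, same length.
#' @return Scalar metric.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse
#' @export
mape <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  if (any(y == 0)) abort("MAPE undefined: observed value of 0")
  100 * mean(abs(y - yhat) / y)
}

#' @rdname rmse
#' @param mape_value A MAPE in percent.
#' @export
accuracy_from_mape <- function(mape_value) 100 - mape_value

regression_metrics <- function(y, yhat) {
  mp <- mape(y, yhat)
  tibble::tibble(n = length(y), rmse = rmse(y, yhat), mape = mp,
                 accuracy = accuracy_from_mape(mp))
}

# Random-forest impurity feature selection: keep features whose normalized
# importance reaches the cutoff (at least the single best feature).
# Returns the kept names and the full normalized importance vector.
# mtry = p: regression forests consider every feature at each split, the
# convention of the reference implementation this analysis follows.
select_features_rf <- function(x, y, rf_trees, cutoff, seed) {
  fit <- ranger::ranger(x = x, y = y, num.trees = rf_trees,
                        importance = "impurity", seed = seed, num.threads = 1,
                        mtry = ncol(x))
  imp <- fit$variable.importance
  total <- sum(imp)
  imp_norm <- if (total > 0) imp / total else
    setNames(rep(1 / length(imp), length(imp)), names(imp))
  kept <- names(imp_norm)[imp_norm >= cutoff]
  if (!length(kept)) kept <- names(which.max(imp_norm))
  list(kept = kept, importance = imp_norm)
}

fit_gbt <- function(x, y, config, seed) {
  xgboost::xgb.train(
    params = list(max_depth = config$gbt$max_depth,
                  eta = config$gbt$learning_rate,
                  objective = "reg:squarederror",
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
    nrounds = config$gbt$n_estimators, verbose = 0
  )
}

regression_xy <- function(features) {
  check_columns(features, c(feature_schema(), "glucose_target", "participant_id"),
                "regression features")
  x <- as.matrix(features[, feature_schema()])
  if (anyNA(x)) abort("feature matrix contains missing values; impute first")
  list(x = x, y = features$glucose_target)
}

#' Leave-one-person-out glucose prediction
#'
#' Population model: for each participant (fold), a random forest is fit on
#' all other participants' rows, features with normalized impurity
#' importance at or above the cutoff are kept, a gradient-boosted tree
#' regressor is fit on the kept features, and the held-out participant is
#' predicted at every epoch. Per-participant RMSE, MAPE and accuracy
#' (100 - MAPE) are reported with their cohort mean and sd. `model =
#' "naive_mean"` / `"naive_median"` replace the learner with the training
#' mean/median predictor under the identical folds, as comparison baselines.
#'
#' @param features Cohort feature table from [cohort_features()] (imputed).
#' @param config A [regressor_config()].
#' @param model `"gbt"`, `"naive_mean"` or `"naive_median"`.
#' @return Object of class `regression_report` with per-fold metrics, the
#'   full prediction table, fold-level selected features and normalized
#'   importances. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_predict_lopocv <- function(features, config = regressor_config(),
                               model = c("gbt", "naive_mean", "naive_median")) {
  model <- match.arg(model)
  xy <- regression_xy(features)
  pids <- sort(unique(features$participant_id))
  if (length(pids) < 2) abort("LOPOCV needs at least 2 participants")
  per_fold <- list()
  preds <- list()
  importances <- list()
  selected <- list()
  for (f in seq_along(pids)) {
    pid <- pids[f]
    test_idx <- which(features$participant_id == pid)
    train_idx <- which(features$participant_id != pid)
    if (!length(test_idx)) {
      warn(sprintf("participant %s has no rows; fold skipped", pid))
      next
    }
    yhat <- fit_fold(xy, train_idx, test_idx, config, model,
                     seed = config$seed + f,
                     store = function(sel, imp) {
                       selected[[as.character(pid)]] <<- sel
                       importances[[as.character(pid)]] <<- imp
                     })
    per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = pid),
      regression_metrics(xy$y[test_idx], yhat)
    )
    preds[[length(preds) + 1L]] <- tibble::tibble(
      participant_id = pid,
      epoch_start = features$epoch_start[test_idx],
      glucose = xy$y[test_idx], predicted = yhat
    )
  }
  new_regression_report(dplyr::bind_rows(per_fold), dplyr::bind_rows(preds),
                        importances, selected, mode = "lopocv", model = model)
}

fit_fold <- function(xy, train_idx, test_idx, config, model, seed, store = NULL) {
  y_tr <- xy$y[train_idx]
  yhat <- if (model == "naive_mean") {
    rep(mean(y_tr), length(test_idx))
  } else if (model == "naive_median") {
    rep(median(y_tr), length(test_idx))
  } else {
    fs <- select_features_rf(xy$x[train_idx, , drop = FALSE], y_tr,
                             config$fs$rf_trees, config$fs$importance_cutoff,
                             seed = seed)
    if (!is.null(store)) store(fs$kept, fs$importance)
    booster <- fit_gbt(xy$x[train_idx, fs$kept, drop = FALSE], y_tr, config, seed)
    predict(booster,
            xgboost::xgb.DMatrix(as.matrix(xy$x[test_idx, fs$kept, drop = FALSE]),
                                 nthread = 1))
  }
  if (!is.null(config$clip)) {
    yhat <- pmin(config$clip[2], pmax(config$clip[1], yhat))
  }
  yhat
}

#' Personalized glucose prediction
#'
#' For each participant, trains on the first contiguous half of their rows
#' in time order (split at `ceiling(n/2)`) and tests on the remaining half,
#' with the same random-forest feature selection and gradient-boosted model
#' as the population pipeline, performed per participant.
#'
#' @inheritParams fit_predict_lopocv
#' @param min_rows Minimum rows a participant needs for a meaningful split.
#' @return A `regression_report` (one fold per participant).
#' @export
fit_predict_personalized <- function(features, config = regressor_config(),
                                     model = c("gbt", "naive_mean", "naive_median"),
                                     min_rows = 48) {
  model <- match.arg(model)
  pids <- sort(unique(features$participant_id))
  per_fold <- list()
  preds <- list()
  importances <- list()
  selected <- list()
  for (f in seq_along(pids)) {
    pid <- pids[f]
    rows <- features[features$participant_id == pid, ]
    rows <- dplyr::arrange(rows, .data$epoch_start)
    if (nrow(rows) < min_rows) {
      abort(sprintf("participant %s has too few rows (%d) for a half split",
                    pid, nrow(rows)))
    }
    xy <- regression_xy(rows)
    split_at <- ceiling(nrow(rows) / 2)
    train_idx <- seq_len(split_at)
    test_idx <- (split_at + 1L):nrow(rows)
    yhat <- fit_fold(xy, train_idx, test_idx, config, model,
                     seed = config$seed + f,
                     store = function(sel, imp) {
                       selected[[as.character(pid)]] <<- sel
                       importances[[as.character(pid)]] <<- imp
                     })
    per_fold[[length(per_fold) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(participant_id = pid),
      regression_metrics(xy$y[test_idx], yhat)
    )
    preds[[length(preds) + 1L]] <- tibble::tibble(
      participant_id = pid, epoch_start = rows$epoch_start[test_idx],
      glucose = xy$y[test_idx], predicted = yhat
    )
  }
  new_regression_report(dplyr::bind_rows(per_fold), dplyr::bind_rows(preds),
                        importances, selected, mode = "personalized", model = model)
}

#' Naive mean/median baselines on a fixed split
#'
#' Predicts the training mean (or median) for every test point and reports
#' the same metrics as the learned models.
#'
#' @param train_y,test_y Observed glucose in the training and test sets.
#' @return Tibble with one row per statistic (`mean`, `median`).
#' @export
naive_baselines <- function(train_y, test_y) {
  stopifnot(length(train_y) >= 1)
  purrr::map_dfr(c(mean = "mean", median = "median"), function(stat) {
    pred <- rep(if (stat == "mean") mean(train_y) else median(train_y),
                length(test_y))
    dplyr::bind_cols(tibble::tibble(baseline = stat),
                     regression_metrics(test_y, pred))
  })
}

new_regression_report <- function(per_fold, predictions, importances,
                                  selected, mode, model) {
  structure(list(
    per_fold = per_fold,
    predictions = predictions,
    importances = importances,
    selected_features = selected,
    summary = tidyr::pivot_longer(per_fold, c("rmse", "mape", "accuracy"),
                                  names_to = "metric") |>
      dplyr::group_by(.data$metric) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       .groups = "drop"),
    mode = mode, model = model
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<regression_report %s/%s> %d folds | RMSE %.2f +/- %.2f mg/dL | MAPE %.2f +/- %.2f%%\n",
    x$mode, x$model, nrow(x$per_fold),
    s$mean[s$metric == "rmse"], s$sd[s$metric == "rmse"],
    s$mean[s$metric == "mape"], s$sd[s$metric == "mape"]
  ))
  invisible(x)
}

#' @rdname fit_predict_lopocv
#' @param x A `regression_report`.
#' @param ... Unused.
#' @export
tidy.regression_report <- function(x, ...) x$per_fold

#' @rdname fit_predict_lopocv
#' @export
glance.regression_report <- function(x, ...) {
  out <- tidyr::pivot_wider(x$summary, names_from = "metric",
                            values_from = c("mean", "sd"),
                            names_glue = "{metric}_{.value}")
  dplyr::bind_cols(tibble::tibble(mode = x$mode, model = x$model,
                                  n_folds = nrow(x$per_fold)), out)
}
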
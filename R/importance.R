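#' Leave-one-person-out impurity importances
#'
#' Fits a random forest regression (impurity importance) on each LOPOCV
#' training set, normalizes each fold's importances to sum to 1, and
#' reports per-feature mean and standard deviation across folds (sd uses
#' n-1; folds = participants).
#'
#' @param features Cohort feature table (imputed) with `glucose_target`.
#' @param rf_trees Trees per forest.
#' @param seed Base seed; fold `f` uses `seed + f`.
#' @return Object of class `importance_report`: a tibble with columns
#'   `feature`, `mean_importance`, `sd_importance` (descending by mean),
#'   carrying the folds-by-features matrix as attribute `fold_importances`.
#' @export
lopocv_importances <- function(features, rf_trees = 1000, seed = 0) {
  xy <- regression_xy(features)
  pids <- sort(unique(features$participant_id))
  if (length(pids) < 2) abort("LOPOCV needs at least 2 participants")
  rows <- list()
  for (f in seq_along(pids)) {
    train_idx <- which(features$participant_id != pids[f])
    if (length(unique(xy$y[train_idx])) < 2) {
      warn(sprintf("degenerate fold for participant %s skipped", pids[f]))
      next
    }
    fs <- select_features_rf(xy$x[train_idx, , drop = FALSE], xy$y[train_idx],
                             rf_trees, cutoff = 0, seed = seed + f)
    rows[[as.character(pids[f])]] <- fs$importance
  }
  mat <- do.call(rbind, rows)
  out <- tibble::tibble(
    feature = colnames(mat),
    mean_importance = colMeans(mat),
    sd_importance = apply(mat, 2, sd)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_importance), .data$feature)
  structure(out, class = c("importance_report", class(out)),
            fold_importances = mat)
}

#' Importance report from an already-fitted population model
#'
#' [fit_predict_lopocv()] stores each fold's normalized impurity importances
#' from its selection forest — the same forests [lopocv_importances()] would
#' fit. This constructor reuses them, avoiding a second pass of
#' leave-one-person-out forest fits.
#'
#' @param report A `regression_report` from [fit_predict_lopocv()] with
#'   `model = "gbt"`.
#' @return An `importance_report`, as from [lopocv_importances()].
#' @export
importance_from_report <- function(report) {
  if (!inherits(report, "regression_report") || !length(report$importances)) {
    abort("report carries no fold importances; run fit_predict_lopocv(model = 'gbt')")
  }
  mat <- do.call(rbind, report$importances)
  out <- tibble::tibble(
    feature = colnames(mat),
    mean_importance = colMeans(mat),
    sd_importance = apply(mat, 2, sd)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_importance), .data$feature)
  structure(out, class = c("importance_report", class(out)),
            fold_importances = mat)
}

#' Aggregate feature importances along the taxonomy axes
#'
#' Sums per-feature mean importances within each group of the three
#' taxonomy axes (category, data source, engineering method) and expresses
#' each group as a percent of the total importance, so each axis sums to
#' 100%.
#'
#' @param importance An `importance_report` (or tibble with `feature` and
#'   `mean_importance`).
#' @param taxonomy Taxonomy tibble, by default [feature_taxonomy()].
#' @return Tibble with columns `axis`, `group`, `percent`.
#' @export
aggregate_importance <- function(importance, taxonomy = feature_taxonomy()) {
  check_columns(importance, c("feature", "mean_importance"), "importance table")
  unmapped <- setdiff(importance$feature, taxonomy$feature)
  if (length(unmapped)) {
    abort(sprintf("taxonomy error: unmapped feature(s) %s",
                  paste(unmapped, collapse = ", ")))
  }
  joined <- dplyr::left_join(tibble::as_tibble(importance), taxonomy,
                             by = "feature")
  total <- sum(joined$mean_importance)
  purrr::map_dfr(c("category", "source", "engineering"), function(axis) {
    dplyr::group_by(joined, group = .data[[axis]]) |>
      dplyr::summarise(percent = 100 * sum(.data$mean_importance) / total,
                       .groups = "drop") |>
      dplyr::mutate(axis = axis, .before = 1) |>
      dplyr::arrange(dplyr::desc(.data$percent))
  })
}

#' Most important features above a mean-importance threshold
#'
#' @param importance An `importance_report`.
#' @param threshold Minimum mean normalized importance (default 0.02, the
#'   cut used for the headline ranking).
#' @return The filtered tibble, sorted by descending mean importance with
#'   ties broken by feature name.
#' @export
top_features <- function(importance, threshold = 0.02) {
  out <- dplyr::filter(tibble::as_tibble(importance),
                       .data$mean_importance > threshold)
  dplyr::arrange(out, dplyr::desc(.data$mean_importance), .data$feature)
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %d features over %d folds; top: %s (%.3f)\n",
              nrow(x), nrow(attr(x, "fold_importances")),
              x$feature[1], x$mean_importance[1]))
  NextMethod()
}

#' @rdname lopocv_importances
#' @param x An `importance_report`.
#' @param ... Unused.
#' @export
tidy.importance_report <- function(x, ...) tibble::as_tibble(x)

#' @rdname lopocv_importances
#' @export
glance.importance_report <- function(x, ...) {
  agg <- aggregate_importance(x)
  cat_top <- agg[agg$axis == "category", ]
  tibble::tibble(
    n_features = nrow(x), n_folds = nrow(attr(x, "fold_importances")),
    top_feature = x$feature[which.max(x$mean_importance)],
    top_category = cat_top$group[which.max(cat_top$percent)],
    top_category_percent = max(cat_top$percent)
  )
}
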
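#' Pipeline configuration
#'
#' Bundles the per-stage configurations. A single `seed` drives every stage:
#' the cohort generator uses `seed`, the classifier `seed + 1`, the
#' regressor `seed + 2` and class balancing `seed + 3`, so one integer
#' reproduces the whole run.
#'
#' @param cohort A [cohort_config()].
#' @param features A [feature_config()].
#' @param labeling List with `min_history_points` and `window_hours`.
#' @param classifier A [classifier_config()].
#' @param regressor A [regressor_config()].
#' @param seed Global seed; when not `NULL` it overrides the stage seeds as
#'   described above.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            features = feature_config(),
                            labeling = list(min_history_points = 144,
                                            window_hours = 24),
                            classifier = classifier_config(),
                            regressor = regressor_config(),
                            seed = NULL) {
  cfg <- structure(list(cohort = cohort, features = features,
                        labeling = labeling, classifier = classifier,
                        regressor = regressor, seed = seed),
                   class = "pipeline_config")
  if (!is.null(seed)) {
    cfg$cohort$seed <- seed
    cfg$classifier$seed <- seed + 1
    cfg$regressor$seed <- seed + 2
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [pipeline_config()]
#' arguments; values override the defaults. Unknown keys at any level are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  merged <- merge_config(defaults, raw, "config")
  if (!is.null(raw$seed)) {
    merged <- do.call(pipeline_config, merged[setdiff(names(merged), "class")])
  }
  merged
}

merge_config <- function(defaults, override, path) {
  if (is.null(override)) return(defaults)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key%s under %s: %s",
                  if (length(unknown) > 1) "s" else "", path,
                  paste(unknown, collapse = ", ")))
  }
  for (key in names(override)) {
    if (is.list(defaults[[key]]) && is.list(override[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]],
                                      paste(path, key, sep = "$"))
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Simulate -> engineer features -> label excursions -> classify -> predict
#' -> rank importances, writing every artifact plus a manifest into
#' `out_dir`. Deterministic given the configuration: two runs with the same
#' config produce byte-identical metric files. A stage failure aborts with
#' the stage name; artifacts of completed stages are left in place.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_cohort Also write the raw simulated cohort directory tree
#'   (large; off by default).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_cohort = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  counts <- list()

  cohort <- stage("simulate", generate_cohort(config$cohort))
  if (write_cohort) write_cohort(cohort, file.path(out_dir, "cohort"))
  counts$participants <- length(cohort)
  counts$glucose_points <- sum(vapply(cohort, function(p) nrow(p$glucose), numeric(1)))

  features <- stage("features", cohort_features(cohort, config$features))
  counts$feature_rows <- nrow(features)

  labels <- stage("label", cohort_labels(
    cohort, min_history_points = config$labeling$min_history_points,
    window_hours = config$labeling$window_hours
  ))
  counts$labeled_points <- sum(!is.na(labels$excursion_label))
  readr::write_csv(class_summary(labels), file.path(out_dir, "class_summary.csv"))

  labeled_features <- join_labels(features, labels)
  counts$labeled_feature_rows <- nrow(labeled_features)
  write_feature_table(labeled_features, file.path(out_dir, "features.csv"))

  balanced <- stage("classify", balance_classes(labeled_features,
                                                seed = config$classifier$seed + 3))
  counts$balanced_rows <- nrow(balanced)
  cv <- stage("classify", run_cv(balanced, config$classifier))
  holdout <- stage("classify", run_holdout(balanced, config$classifier))
  write_metrics_json(list(
    cv = list(summary = df_to_list(cv$summary),
              fold_metrics = df_to_list(cv$fold_metrics),
              confusion = unclass(cv$confusion)),
    holdout = list(
      decision_tree = holdout_to_list(holdout$decision_tree),
      logistic = holdout_to_list(holdout$logistic)
    )
  ), file.path(out_dir, "classification.json"))

  reg <- stage("predict", list(
    lopocv = fit_predict_lopocv(features, config$regressor),
    personalized = fit_predict_personalized(features, config$regressor),
    naive_mean = fit_predict_lopocv(features, config$regressor, model = "naive_mean"),
    naive_median = fit_predict_lopocv(features, config$regressor, model = "naive_median")
  ))
  write_metrics_json(
    lapply(reg, function(r) list(per_fold = df_to_list(r$per_fold),
                                 summary = df_to_list(r$summary))),
    file.path(out_dir, "regression.json")
  )
  readr::write_csv(reg$lopocv$predictions,
                   file.path(out_dir, "predictions_lopocv.csv"))

  # the LOPOCV selection forests already carry the per-fold importances
  imp <- stage("importance", importance_from_report(reg$lopocv))
  agg <- aggregate_importance(imp)
  write_metrics_json(list(
    per_feature = df_to_list(tibble::as_tibble(imp)),
    aggregated = df_to_list(agg),
    top_features = df_to_list(top_features(imp))
  ), file.path(out_dir, "importance.json"))

  manifest <- list(
    package = "glucowear",
    version = as.character(utils::packageVersion("glucowear")),
    config_hash = rlang::hash(config),
    seed = config$seed,
    row_counts = counts
  )
  write_metrics_json(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(cohort = cohort, features = features, labels = labels,
                 cv = cv, holdout = holdout, regression = reg,
                 importance = imp, aggregated = agg, manifest = manifest))
}

df_to_list <- function(df) lapply(as.list(df), unname)

holdout_to_list <- function(h) {
  list(metrics = h$metrics, confusion = unclass(h$confusion),
       per_class_accuracy = as.list(h$per_class_accuracy))
}

write_metrics_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}
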
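#' Plot a labeled glucose trace
#'
#' CGM trace with the rolling 24-h mean +/- 1 sd band and points colored by
#' personalized excursion class.
#'
#' @param labeled Output of [label_glucose()].
#' @return A ggplot object.
#' @export
plot_glucose_labels <- function(labeled) {
  check_columns(labeled, c("time", "glucose_mg_dl", "roll_mean", "roll_sd",
                           "excursion_label"), "labeled glucose")
  df <- dplyr::mutate(labeled, hours = (.data$time - min(.data$time)) / 3600)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$roll_mean - .data$roll_sd,
                                      ymax = .data$roll_mean + .data$roll_sd),
                         fill = "grey85", na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$roll_mean),
                       color = "grey50", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$glucose_mg_dl,
                                     color = .data$excursion_label),
                        size = 0.6, na.rm = TRUE) +
    ggplot2::scale_color_manual(
      values = c(PersLow = "#368f8b", PersNorm = "grey40", PersHigh = "#7b4b94"),
      na.value = "grey80", name = NULL
    ) +
    ggplot2::labs(x = "Hours of wear", y = "Interstitial glucose (mg/dL)") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param confusion 3x3 confusion matrix (rows = truth).
#' @return A ggplot object.
#' @export
plot_confusion <- function(confusion) {
  df <- tibble::as_tibble(as.table(confusion), .name_repair = "minimal")
  names(df) <- c("truth", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_gradient(low = "#9ecae1", high = "#08306b") +
    ggplot2::labs(x = "Predicted", y = "Observed") +
    ggplot2::theme_minimal()
}

#' @rdname run_cv
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$fold_metrics, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "#9ecae1") +
    ggplot2::labs(x = NULL, y = "Fold metric") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname fit_predict_lopocv
#' @param object A `regression_report`.
#' @export
autoplot.regression_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$glucose, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "red") +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "Observed glucose (mg/dL)",
                  y = "Predicted glucose (mg/dL)") +
    ggplot2::theme_minimal()
}

#' @rdname lopocv_importances
#' @param object An `importance_report`.
#' @param n_top Features shown.
#' @export
autoplot.importance_report <- function(object, n_top = 15, ...) {
  df <- utils::head(tibble::as_tibble(object), n_top)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = pmax(0, .data$mean_importance - .data$sd_importance),
                   xmax = .data$mean_importance + .data$sd_importance),
      height = 0.3
    ) +
    ggplot2::labs(x = "Mean impurity importance (normalized)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Donut chart of aggregated importance
#'
#' Two concentric rings: feature categories (outer) and data sources
#' (inner), each as percent of total importance.
#'
#' @param aggregated Output of [aggregate_importance()].
#' @return A ggplot object.
#' @export
plot_importance_donut <- function(aggregated) {
  df <- dplyr::filter(aggregated, .data$axis %in% c("category", "source"))
  df$ring <- ifelse(df$axis == "category", 2, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ring, y = .data$percent,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 0.9, color = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::xlim(0, 2.6) +
    ggplot2::labs(fill = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
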
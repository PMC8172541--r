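#' Label glucose readings against a personalized rolling 24-h baseline
#'
#' Classifies each interstitial glucose reading as `PersHigh` (above one
#' standard deviation over the mean of the participant's previous 24 h),
#' `PersLow` (below one standard deviation under that mean) or `PersNorm`
#' (within one standard deviation, boundaries inclusive). The rolling mean
#' and sample (n-1) standard deviation are computed over the readings in
#' `[t - 24 h, t)` — the point being labeled is excluded. Points with fewer
#' than `min_history_points` readings in their window are left unlabeled
#' (`NA`) and should be excluded downstream; by default that drops roughly
#' the first 12 h of wear.
#'
#' @param glucose Tibble with columns `time` (seconds) and `glucose_mg_dl`.
#' @param min_history_points Minimum readings required in the prior-24-h
#'   window (default 144 = 12 h of 5-min readings).
#' @param window_hours Width of the rolling baseline window.
#' @return The input tibble plus columns `roll_mean`, `roll_sd` and
#'   `excursion_label` (factor with levels PersLow, PersNorm, PersHigh).
#' @export
label_glucose <- function(glucose, min_history_points = 144,
                          window_hours = 24) {
  validate_glucose(glucose)
  n <- nrow(glucose)
  t <- glucose$time
  g <- glucose$glucose_mg_dl
  roll_mean <- rep(NA_real_, n)
  roll_sd <- rep(NA_real_, n)
  w <- window_hours * 3600
  # first index with time >= t - w (window closed on the left)
  lo_idx <- findInterval(t - w, t, left.open = TRUE) + 1L
  for (i in seq_len(n)) {
    lo <- lo_idx[i]
    if (lo > i - 1L) next
    win <- g[lo:(i - 1L)]
    if (length(win) < min_history_points) next
    roll_mean[i] <- mean(win)
    roll_sd[i] <- sd(win)
  }
  label <- rep(NA_character_, n)
  hi <- roll_mean + roll_sd
  lo_b <- roll_mean - roll_sd
  ok <- !is.na(roll_mean)
  label[ok & g > hi] <- "PersHigh"
  label[ok & g < lo_b] <- "PersLow"
  label[ok & g >= lo_b & g <= hi] <- "PersNorm"
  if (!any(ok)) {
    warn("series shorter than the minimum history; no points labeled")
  }
  dplyr::mutate(glucose,
                roll_mean = roll_mean, roll_sd = roll_sd,
                excursion_label = factor(label, levels = excursion_levels()))
}

#' Label glucose for every participant of a cohort
#'
#' @param cohort List of [participant_record()]s.
#' @param ... Passed to [label_glucose()].
#' @return Tibble with `participant_id` plus the [label_glucose()] columns.
#' @export
cohort_labels <- function(cohort, ...) {
  dplyr::bind_rows(lapply(cohort, function(p) {
    dplyr::mutate(label_glucose(p$glucose, ...),
                  participant_id = p$participant_id, .before = 1)
  }))
}

#' Distribution summary of each excursion class
#'
#' Per-class moments of the labeled glucose values: mean, sample sd, range,
#' adjusted Fisher-Pearson skewness, excess kurtosis, and the
#' Kolmogorov-Smirnov statistic of the class sample against a normal
#' distribution with the class's own fitted mean and sd. Classes with fewer
#' than 2 points are reported with missing moments.
#'
#' @param labeled Output of [label_glucose()] or [cohort_labels()].
#' @return Tibble with one row per class.
#' @export
class_summary <- function(labeled) {
  check_columns(labeled, c("glucose_mg_dl", "excursion_label"), "labeled glucose")
  purrr::map_dfr(excursion_levels(), function(cls) {
    x <- labeled$glucose_mg_dl[!is.na(labeled$excursion_label) &
                                 labeled$excursion_label == cls]
    if (length(x) < 2) {
      return(tibble::tibble(class = cls, n = length(x), mean = NA_real_,
                            sd = NA_real_, min = NA_real_, max = NA_real_,
                            skewness = NA_real_, kurtosis = NA_real_,
                            ks_stat = NA_real_))
    }
    ks <- suppressWarnings(
      ks.test(x, "pnorm", mean = mean(x), sd = sd(x))$statistic
    )
    tibble::tibble(
      class = cls, n = length(x), mean = mean(x), sd = sd(x),
      min = min(x), max = max(x),
      skewness = sample_skewness(x), kurtosis = sample_kurtosis(x),
      ks_stat = unname(ks)
    )
  })
}

#' Attach excursion labels to a feature table
#'
#' Joins the per-participant labels onto the assembled feature rows by
#' participant and epoch, keeping only rows that carry a label.
#'
#' @param features Feature table from [cohort_features()].
#' @param labels Labels from [cohort_labels()].
#' @return Feature table with an `excursion_label` column.
#' @export
join_labels <- function(features, labels) {
  lab <- dplyr::select(labels, "participant_id",
                       epoch_start = "time", "excursion_label")
  out <- dplyr::inner_join(features, lab,
                           by = c("participant_id", "epoch_start"))
  dplyr::filter(out, !is.na(.data$excursion_label))
}
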
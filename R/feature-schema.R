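#' The registered 69-feature schema
#'
#' Names of the 69 historical features computed for every 5-minute epoch, in
#' stable column order. The groups (counts sum to 69):
#'
#' * 28 data-driven: 7 summary statistics (mean, sd, min, max, q1, q3, skew)
#'   for each of heart rate, accelerometry vector magnitude, electrodermal
#'   activity and skin temperature over the most recent historical epoch;
#' * 8 heart-rate-variability metrics from the inter-beat intervals
#'   (mean/median/max/min IBI, SDNN, RMSSD, NN50, pNN50);
#' * 3 electrodermal peak features (peaks in the epoch, total and mean peaks
#'   per 5-min over the previous 2 h);
#' * 5 activity features (activity-bout indicator, bouts in the previous 1 h,
#'   mean bouts over the previous 24 h, ACC vector-magnitude mean and max
#'   over the previous 2 h);
#' * 3 circadian features (minutes from midnight, hours from midnight, wake
#'   time);
#' * 19 food features (calories/protein/carbs/sugar sums over 2/8/24 h,
#'   eating-event indicator, eating-event counts and means over 2/8/24 h);
#' * 2 demographics (sex, HbA1c);
#' * 1 personalization feature (the participant id as a model input).
#'
#' This enumeration reconstructs the full feature list from the described
#' feature-engineering procedure and the names used in the importance
#' ranking; the original study's complete list appears only in its
#' supplementary material.
#'
#' @return Character vector of length 69.
#' @export
feature_schema <- function() {
  stat7 <- c("mean", "sd", "min", "max", "q1", "q3", "skew")
  c(
    paste0("hr_", stat7),
    paste0("acc_", stat7),
    paste0("eda_", stat7),
    paste0("temp_", stat7),
    c("ibi_mean", "ibi_median", "ibi_max", "ibi_min",
      "sdnn", "rmssd", "nn50", "pnn50"),
    c("eda_peaks", "eda_peaks_total_2h", "eda_peaks_mean_2h"),
    c("activity_bout", "activity_bouts_1h", "activity_bouts_24h",
      "acc_vm_mean_2h", "acc_vm_max_2h"),
    c("minutes_from_midnight", "hours_from_midnight", "wake_time"),
    paste0(rep(c("calories", "protein", "carbs", "sugar"), each = 3),
           "_", rep(c("2h", "8h", "24h"), 4)),
    c("eating_event", "eating_count_2h", "eating_count_8h", "eating_count_24h",
      "eating_mean_2h", "eating_mean_8h", "eating_mean_24h"),
    c("sex", "hba1c"),
    "personalization"
  )
}

#' Feature taxonomy
#'
#' Maps each of the 69 features to one value on each of three axes:
#' `category` (food, circadian rhythm, stress, activity, temperature, heart
#' rate, electrodermal activity, biological sex, HbA1c, personalization),
#' `source` (food log, wearable, user input, model) and `engineering`
#' (data-driven, domain-driven, other). Shipped as a versioned CSV under
#' `inst/extdata/` so the mapping is inspectable and testable.
#'
#' @return A tibble with columns `feature`, `category`, `source`,
#'   `engineering`, one row per registered feature.
#' @export
feature_taxonomy <- function() {
  path <- system.file("extdata", "feature_taxonomy.csv", package = "glucowear")
  tax <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  schema <- feature_schema()
  missing <- setdiff(schema, tax$feature)
  if (length(missing)) {
    abort(sprintf("taxonomy error: unmapped feature(s) %s",
                  paste(missing, collapse = ", ")))
  }
  tax[match(schema, tax$feature), ]
}

excursion_levels <- function() c("PersLow", "PersNorm", "PersHigh")
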
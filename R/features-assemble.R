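#' Feature-engineering options
#'
#' @param tz_offset Seconds added to UTC to obtain local wall-clock time
#'   (used by the circadian and wake-time features).
#' @param wake_slope_threshold Slope threshold for [detect_wake_times()].
#' @param imputation `"ffill"` (default): participant-wise forward fill,
#'   then remaining head missing values take the column's first observed
#'   value (kept causal so no feature reads data from after its target);
#'   `"none"`: leave `NA`s in place.
#' @return List of class `feature_config`.
#' @export
feature_config <- function(tz_offset = 0, wake_slope_threshold = 0.02,
                           imputation = c("ffill", "none")) {
  structure(list(tz_offset = tz_offset,
                 wake_slope_threshold = wake_slope_threshold,
                 imputation = match.arg(imputation)),
            class = "feature_config")
}

# Seven summary stats per 5-min epoch for one channel. Returns an
# n_epochs x 7 tibble; epochs with < 2 samples are all-NA.
epoch_stats <- function(times, values, origin, n_epochs, prefix) {
  idx <- epoch_index(times, origin)
  ok <- idx >= 1L & idx <= n_epochs & !is.na(values)
  cols <- paste0(prefix, "_", c("mean", "sd", "min", "max", "q1", "q3", "skew"))
  m <- matrix(NA_real_, nrow = n_epochs, ncol = 7, dimnames = list(NULL, cols))
  if (any(ok)) {
    sp <- split(values[ok], idx[ok])
    stats <- vapply(sp, summary_stats, numeric(7))
    m[as.integer(names(sp)), ] <- t(stats)
  }
  tibble::as_tibble(m)
}

# Per-epoch HRV metrics from the IBI event list.
epoch_hrv <- function(ibi, origin, n_epochs) {
  cols <- c("ibi_mean", "ibi_median", "ibi_max", "ibi_min",
            "sdnn", "rmssd", "nn50", "pnn50")
  m <- matrix(NA_real_, nrow = n_epochs, ncol = 8, dimnames = list(NULL, cols))
  if (nrow(ibi)) {
    abs_t <- (attr(ibi, "start_time") %||% origin) + ibi$offset_s
    idx <- epoch_index(abs_t, origin)
    ok <- idx >= 1L & idx <= n_epochs
    if (any(ok)) {
      sp <- split(ibi$interval_s[ok], idx[ok])
      stats <- vapply(sp, hrv_metrics, numeric(8))
      m[as.integer(names(sp)), ] <- t(stats)
    }
  }
  tibble::as_tibble(m)
}

# Per-epoch EDA unique-peak counts.
epoch_eda_peaks <- function(eda, origin, n_epochs) {
  idx <- epoch_index(eda$time, origin)
  ok <- idx >= 1L & idx <= n_epochs
  counts <- integer(n_epochs)
  if (any(ok)) {
    sp <- split(eda$value[ok], idx[ok])
    counts[as.integer(names(sp))] <- vapply(sp, detect_eda_peaks, integer(1))
  }
  counts
}

#' Assemble the per-epoch feature table for one participant
#'
#' Builds one row per CGM glucose timestamp with at least 24 h of prior
#' history, holding the 69 registered historical features (see
#' [feature_schema()]) plus the glucose target. Every feature for a target
#' at time `t` uses only data from before `t`: per-epoch sensor summaries
#' come from the epoch labeled `t - 5 min` (covering `[t - 5 min, t)`),
#' and all rolling windows are half-open `[t - w, t)`. The wake-time
#' feature carries the wake time detected on the most recent fully elapsed
#' local day. Rows inside the first 24 h of wear are dropped.
#'
#' @param p A [participant_record()].
#' @param config A [feature_config()].
#' @return Feature-table tibble with columns `participant_id`,
#'   `epoch_start`, the 69 features and `glucose_target`.
#' @export
assemble_features <- function(p, config = feature_config()) {
  glucose <- p$glucose
  if (!nrow(glucose) ||
      max(glucose$time) - min(glucose$time) < 86400) {
    warn(sprintf("participant %d has < 24 h of data; empty feature table",
                 p$participant_id))
    return(empty_feature_table())
  }
  origin <- min(glucose$time)
  n_epochs <- as.integer(floor((max(glucose$time) - origin) / EPOCH_SECONDS)) + 1L
  grid <- origin + (seq_len(n_epochs) - 1) * EPOCH_SECONDS

  hr <- p$streams$HR
  acc <- p$streams$ACC
  eda <- p$streams$EDA
  temp <- p$streams$TEMP
  acc_vm <- vector_magnitude(acc$x, acc$y, acc$z)

  E <- dplyr::bind_cols(
    tibble::tibble(epoch_start = grid),
    epoch_stats(hr$time, hr$value, origin, n_epochs, "hr"),
    epoch_stats(acc$time, acc_vm, origin, n_epochs, "acc"),
    epoch_stats(eda$time, eda$value, origin, n_epochs, "eda"),
    epoch_stats(temp$time, temp$value, origin, n_epochs, "temp"),
    epoch_hrv(p$ibi, origin, n_epochs)
  )
  E$eda_peaks <- epoch_eda_peaks(eda, origin, n_epochs)
  E$activity_bout <- activity_bout_indicator(E$acc_mean, E$hr_mean)

  w2h <- as.integer(2 * 3600 / EPOCH_SECONDS)    # 24 epochs
  w1h <- as.integer(3600 / EPOCH_SECONDS)        # 12 epochs
  w24h <- as.integer(86400 / EPOCH_SECONDS)      # 288 epochs

  # rolling features are indexed by grid position i: windows are the
  # epochs (i - w):(i - 1), i.e. [t - w, t) for target t = grid[i]
  roll <- tibble::tibble(
    eda_peaks_total_2h = roll_prior(E$eda_peaks, w2h, "sum", empty = 0),
    eda_peaks_mean_2h = roll_prior(E$eda_peaks, w2h, "mean", empty = 0),
    activity_bouts_1h = roll_prior(E$activity_bout, w1h, "sum", empty = 0),
    activity_bouts_24h = roll_prior(E$activity_bout, w24h, "mean", empty = 0),
    acc_vm_mean_2h = roll_prior(E$acc_mean, w2h, "mean"),
    acc_vm_max_2h = roll_prior(E$acc_max, w2h, "max")
  )

  wake_by_day <- detect_wake_times(
    E[, c("epoch_start", "acc_mean", "acc_sd", "hr_mean", "hr_sd")],
    tz_offset = config$tz_offset,
    slope_threshold = config$wake_slope_threshold
  )
  # feature at t = wake of the most recent fully elapsed local day
  # (carrying the last detected value across undetected days)
  carried <- wake_by_day$wake_minutes
  for (j in seq_along(carried)) {
    if (is.na(carried[j]) && j > 1) carried[j] <- carried[j - 1]
  }
  day_of <- floor((grid + config$tz_offset) / 86400)
  prev_day_pos <- match(day_of - 1, wake_by_day$day)
  wake_feature <- carried[prev_day_pos]

  # target rows: observed glucose with >= 24 h of prior wear
  target_i <- epoch_index(glucose$time, origin)
  keep <- glucose$time >= origin + 86400 & target_i >= 1L & target_i <= n_epochs
  ti <- target_i[keep]
  t_abs <- glucose$time[keep]

  circ <- circadian_features(t_abs, config$tz_offset)
  food <- food_features(p$food, t_abs)

  stat_cols <- setdiff(names(E), c("epoch_start", "activity_bout", "eda_peaks"))
  tbl <- dplyr::bind_cols(
    tibble::tibble(participant_id = p$participant_id, epoch_start = t_abs),
    E[ti - 1L, c(stat_cols, "eda_peaks", "activity_bout")],
    roll[ti, ],
    circ,
    tibble::tibble(wake_time = wake_feature[ti]),
    food,
    tibble::tibble(sex = p$sex, hba1c = p$hba1c,
                   personalization = as.numeric(p$participant_id),
                   glucose_target = glucose$glucose_mg_dl[keep])
  )
  tbl <- tbl[, feature_table_columns()]
  if (config$imputation == "ffill") tbl <- impute_ffill(tbl) else tbl
}

empty_feature_table <- function() {
  cols <- feature_table_columns()
  out <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
  out$participant_id <- integer(0)
  out
}

# Causal imputation: forward fill, then head NAs take the first observed
# value of the column (whole-column NA becomes 0).
impute_ffill <- function(tbl) {
  for (col in feature_schema()) {
    v <- tbl[[col]]
    if (!anyNA(v)) next
    obs <- which(!is.na(v))
    if (!length(obs)) {
      tbl[[col]] <- rep(0, length(v))
      next
    }
    v_f <- v
    last <- NA_real_
    for (j in seq_along(v_f)) {
      if (is.na(v_f[j])) v_f[j] <- last else last <- v_f[j]
    }
    if (is.na(v_f[1])) {
      first_val <- v[obs[1]]
      v_f[seq_len(obs[1] - 1)] <- first_val
    }
    tbl[[col]] <- v_f
  }
  tbl
}

#' Assemble feature tables for a whole cohort
#'
#' @param cohort List of [participant_record()]s.
#' @param config A [feature_config()].
#' @return One feature-table tibble with all participants' rows.
#' @export
cohort_features <- function(cohort, config = feature_config()) {
  dplyr::bind_rows(lapply(cohort, assemble_features, config = config))
}
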
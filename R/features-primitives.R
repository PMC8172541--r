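#' Count electrodermal-activity peaks
#'
#' Counts "unique peaks" in a skin-conductance window: local maxima that
#' survive a minimum inter-peak separation (when two candidates are closer
#' than `min_distance` samples the higher one is kept, ties going to the
#' earlier) and whose topographic prominence is at least `min_prominence`
#' micro-siemens. Prominence is the height of the maximum above the higher
#' of the two minima separating it from the nearest taller sample on each
#' side (window edges acting as bases where no taller sample exists). The
#' defaults — 4 samples (1 s at the device's 4 Hz) and 0.3 uS — are the
#' sudomotor-response conventions used throughout the package.
#'
#' @param x Numeric vector of EDA samples (micro-siemens).
#' @param min_distance Minimum separation between kept peaks, in samples.
#' @param min_prominence Minimum topographic prominence (micro-siemens).
#' @param positions If `TRUE`, return kept peak indices instead of the count.
#' @return Integer count (or integer vector of indices).
#' @export
detect_eda_peaks <- function(x, min_distance = 4L, min_prominence = 0.3,
                             positions = FALSE) {
  n <- length(x)
  empty <- if (positions) integer(0) else 0L
  if (n < 3 || anyNA(x)) {
    if (anyNA(x)) x <- x[!is.na(x)]
    n <- length(x)
    if (n < 3) return(empty)
  }
  cand <- local_maxima(x)
  if (!length(cand)) return(empty)
  # enforce min separation: keep higher candidate, ties to the earlier
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  # cheap upper bound: prominence can never exceed height - global minimum
  kept <- kept[x[kept] - min(x) >= min_prominence]
  if (!length(kept)) return(empty)
  prom <- vapply(kept, function(i) peak_prominence(x, i), numeric(1))
  kept <- kept[prom >= min_prominence]
  if (positions) kept else length(kept)
}

# Indices of local maxima; plateaus yield their first index.
local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_max <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  starts[mid][is_max]
}

peak_prominence <- function(x, i) {
  h <- x[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && x[j] <= h) {
    if (x[j] < left_min) left_min <- x[j]
    j <- j - 1L
  }
  right_min <- h
  j <- i + 1L
  n <- length(x)
  while (j <= n && x[j] <= h) {
    if (x[j] < right_min) right_min <- x[j]
    j <- j + 1L
  }
  h - max(left_min, right_min)
}

#' Heart-rate-variability metrics of an interval window
#'
#' Computes the 8 HRV summaries of the inter-beat intervals falling in a
#' 5-min epoch: mean, median, maximum and minimum interval; SDNN (sample
#' standard deviation of intervals); RMSSD (root mean square of successive
#' interval differences); NN50 (number of successive differences exceeding
#' 50 ms); and pNN50 (NN50 divided by the total number of intervals — the
#' denominator is the interval count, not the difference count). All
#' interval statistics are in milliseconds. Fewer than 2 intervals leave the
#' variability metrics missing; an empty window leaves all 8 missing.
#'
#' @param intervals_s Numeric vector of inter-beat intervals in seconds.
#' @return Named numeric vector of length 8 (`ibi_mean`, `ibi_median`,
#'   `ibi_max`, `ibi_min`, `sdnn`, `rmssd`, `nn50`, `pnn50`).
#' @export
hrv_metrics <- function(intervals_s) {
  ms <- intervals_s[!is.na(intervals_s)] * 1000
  out <- setNames(rep(NA_real_, 8),
                  c("ibi_mean", "ibi_median", "ibi_max", "ibi_min",
                    "sdnn", "rmssd", "nn50", "pnn50"))
  n <- length(ms)
  if (n == 0) return(out)
  out["ibi_mean"] <- mean(ms)
  out["ibi_median"] <- median(ms)
  out["ibi_max"] <- max(ms)
  out["ibi_min"] <- min(ms)
  if (n >= 2) {
    d <- diff(ms)
    out["sdnn"] <- sd(ms)
    out["rmssd"] <- sqrt(mean(d^2))
    out["nn50"] <- sum(abs(d) > 50)
    out["pnn50"] <- out["nn50"] / n
  }
  out
}

#' Circadian clock features
#'
#' Local wall-clock minutes and hours elapsed since midnight for absolute
#' UTC timestamps, given a fixed timezone offset.
#'
#' @param time UTC epoch seconds.
#' @param tz_offset Seconds added to UTC to obtain local time.
#' @return A tibble with columns `minutes_from_midnight` (in `[0, 1440)`)
#'   and `hours_from_midnight`.
#' @export
circadian_features <- function(time, tz_offset = 0) {
  minutes <- ((time + tz_offset) %% 86400) / 60
  tibble::tibble(minutes_from_midnight = minutes,
                 hours_from_midnight = minutes / 60)
}

#' Activity-bout indicator
#'
#' An epoch is an activity bout when both its mean accelerometry vector
#' magnitude and its mean heart rate exceed the participant's expanding
#' average over all prior epochs. The first epoch (no history) is never a
#' bout, and epochs with a missing mean are never bouts.
#'
#' @param acc_mean,hr_mean Per-epoch mean ACC vector magnitude and heart
#'   rate, on the uniform epoch grid, in chronological order.
#' @return Integer 0/1 vector of the same length.
#' @export
activity_bout_indicator <- function(acc_mean, hr_mean) {
  n <- length(acc_mean)
  stopifnot(length(hr_mean) == n)
  out <- integer(n)
  for (j in seq_len(n)) {
    if (j == 1L || is.na(acc_mean[j]) || is.na(hr_mean[j])) next
    pa <- acc_mean[seq_len(j - 1L)]
    ph <- hr_mean[seq_len(j - 1L)]
    pa <- pa[!is.na(pa)]
    ph <- ph[!is.na(ph)]
    if (!length(pa) || !length(ph)) next
    if (acc_mean[j] > mean(pa) && hr_mean[j] > mean(ph)) out[j] <- 1L
  }
  out
}

#' Per-day wake-time detection
#'
#' For each local calendar day, flags every 5-min epoch `0` when at least
#' two of four movement/cardiac measures (ACC vector-magnitude mean and sd,
#' heart-rate mean and sd) fall below that day's average, `1` otherwise;
#' smooths the flags with a 3-h trailing rolling mean; and takes the wake
#' time as the earliest epoch where the smoothed series' first difference
#' exceeds `slope_threshold` while the smoothed values 25 and 75 minutes
#' later both exceed the value at the candidate. Days where no epoch
#' satisfies the criteria get `NA`.
#'
#' @param epochs Tibble with columns `epoch_start` (UTC seconds, uniform
#'   5-min grid) and `acc_mean`, `acc_sd`, `hr_mean`, `hr_sd`.
#' @param tz_offset Seconds added to UTC for local time.
#' @param slope_threshold Minimum first difference of the smoothed series,
#'   per epoch.
#' @return Tibble with one row per day: `day` (local day index),
#'   `wake_minutes` (minutes from midnight, `NA` when undetected).
#' @export
detect_wake_times <- function(epochs, tz_offset = 0, slope_threshold = 0.02) {
  check_columns(epochs, c("epoch_start", "acc_mean", "acc_sd", "hr_mean", "hr_sd"),
                "wake-time input")
  local_t <- epochs$epoch_start + tz_offset
  day <- floor(local_t / 86400)
  smooth_w <- as.integer(3 * 3600 / EPOCH_SECONDS)  # 36 epochs
  purrr::map_dfr(split(seq_along(day), day), function(idx) {
    m <- as.matrix(epochs[idx, c("acc_mean", "acc_sd", "hr_mean", "hr_sd")])
    day_avg <- colMeans(m, na.rm = TRUE)
    below <- sweep(m, 2, day_avg, `<`)
    n_below <- rowSums(below, na.rm = TRUE)
    indicator <- as.numeric(n_below < 2)  # 0 = likely asleep, 1 = active
    nd <- length(indicator)
    smoothed <- vapply(seq_len(nd), function(i) {
      mean(indicator[max(1L, i - smooth_w + 1L):i])
    }, numeric(1))
    wake_minutes <- NA_real_
    look25 <- as.integer(25 * 60 / EPOCH_SECONDS)
    look75 <- as.integer(75 * 60 / EPOCH_SECONDS)
    for (i in 2:max(2, nd - look75)) {
      if (i + look75 > nd) break
      if (smoothed[i] - smoothed[i - 1] > slope_threshold &&
          smoothed[i + look25] > smoothed[i] &&
          smoothed[i + look75] > smoothed[i]) {
        wake_minutes <- (local_t[idx[i]] %% 86400) / 60
        break
      }
    }
    tibble::tibble(day = day[idx[1]], wake_minutes = wake_minutes)
  })
}

#' Rolling food-log features at a target time
#'
#' For a target time `t`, sums calories, protein, carbohydrates and sugar
#' over the historical windows `[t - w, t)` for w = 2, 8 and 24 h; flags
#' whether an eating event fell in the most recent historical epoch
#' `[t - 5 min, t)`; and counts eating events over the three windows plus
#' their per-epoch averages (count divided by the number of 5-min epochs in
#' the window). An empty log yields all zeros.
#'
#' @param food Food-log tibble (see [read_food_log()]).
#' @param t Vector of target times (UTC epoch seconds).
#' @return Tibble with one row per target time and the 19 food columns of
#'   [feature_schema()].
#' @export
food_features <- function(food, t) {
  windows_h <- c(2, 8, 24)
  out <- tibble::tibble(.rows = length(t))
  ft <- food$time
  for (w in windows_h) {
    sel <- lapply(t, function(tt) which(ft >= tt - w * 3600 & ft < tt))
    tag <- paste0(w, "h")
    out[[paste0("calories_", tag)]] <-
      vapply(sel, function(s) sum(food$calories_kcal[s]), numeric(1))
    out[[paste0("protein_", tag)]] <-
      vapply(sel, function(s) sum(food$protein_g[s]), numeric(1))
    out[[paste0("carbs_", tag)]] <-
      vapply(sel, function(s) sum(food$carbs_g[s]), numeric(1))
    out[[paste0("sugar_", tag)]] <-
      vapply(sel, function(s) sum(food$sugar_g[s]), numeric(1))
    cnt <- lengths(sel)
    out[[paste0("eating_count_", tag)]] <- as.numeric(cnt)
    out[[paste0("eating_mean_", tag)]] <- cnt / (w * 3600 / EPOCH_SECONDS)
  }
  out$eating_event <- vapply(
    t, function(tt) as.numeric(any(ft >= tt - EPOCH_SECONDS & ft < tt)), numeric(1)
  )
  nutr_cols <- paste0(rep(c("calories", "protein", "carbs", "sugar"), each = 3),
                      "_", rep(c("2h", "8h", "24h"), 4))
  out[, c(nutr_cols, "eating_event",
          paste0("eating_count_", c("2h", "8h", "24h")),
          paste0("eating_mean_", c("2h", "8h", "24h")))]
}
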
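#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: 16 participants
#' wearing the devices 8-10 days, glucose sampled every 5 min (~1500 retained
#' points per participant once wear gaps are applied), meal-driven glucose
#' rises, activity-driven dips, a circadian baseline, and stochastic
#' electrodermal stress bursts. Magnitudes that the source study does not
#' report (it publishes no distributional parameters of its raw streams) are
#' stand-ins chosen once for physiological plausibility; see the package
#' vignette.
#'
#' @param n_participants Number of participants (>= 2).
#' @param days Days of wear per participant: a single value, a vector of
#'   length `n_participants`, or `NULL` to draw uniformly from `days_range`.
#' @param days_range Integer range days are drawn from when `days` is `NULL`.
#' @param seed Integer RNG seed; every source of randomness flows from it.
#' @param glucose_baseline Per-participant mean glucose drawn from
#'   `N(mean, sd)` (mg/dL).
#' @param circadian_amp Amplitude of the 24-h sinusoidal glucose component
#'   (mg/dL).
#' @param circadian_peak_hour Local hour of the sinusoid's maximum.
#' @param meal_response List: `peak_per_g_sugar` and `peak_per_g_carb`
#'   (mg/dL rise at kernel peak per gram), `lag_min` (time to peak) and
#'   `decay_min` (decay scale) of the log-normal-shaped meal kernel.
#' @param activity_dip List: `drop_mg_dl` (glucose drop during a bout),
#'   `lag_min` (onset lag) and `recovery_min` (exponential recovery scale).
#' @param noise List: `ar1` coefficient and innovation `sd` (mg/dL) of the
#'   AR(1) glucose noise.
#' @param meals_per_day Expected logged eating events per day.
#' @param bouts_per_day Planted activity bouts per day.
#' @param bout_duration_min Length-2 range of bout durations (minutes).
#' @param stress_bursts_per_day Expected planted EDA burst events per day.
#' @param eda_burst_amp List: `mean` and `sd` of burst peak amplitude
#'   (micro-siemens); the default centres peak prominence near 0.5 uS.
#' @param wear_gap_fraction Fraction of CGM epochs dropped at random; the
#'   default 0.42 yields ~1500 retained glucose points for a 9-day wear.
#' @param hr_baseline List: `mean`, `sd` of per-participant resting heart
#'   rate, plus `bout_delta` (bpm added during bouts) and `noise_sd`.
#' @param rates Named sampling rates in Hz for HR, EDA, TEMP, ACC. The
#'   device rates (1, 4, 4, 32) are the defaults.
#' @param tz_offset Seconds added to UTC to obtain local wall-clock time.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 16,
                          days = NULL,
                          days_range = c(8L, 10L),
                          seed = 1L,
                          glucose_baseline = list(mean = 110, sd = 8),
                          circadian_amp = 8,
                          circadian_peak_hour = 16,
                          meal_response = list(peak_per_g_sugar = 0.8,
                                               peak_per_g_carb = 0.3,
                                               lag_min = 30, decay_min = 90),
                          activity_dip = list(drop_mg_dl = 15, lag_min = 5,
                                              recovery_min = 30),
                          noise = list(ar1 = 0.7, sd = 3),
                          meals_per_day = 4,
                          bouts_per_day = 3,
                          bout_duration_min = c(20, 40),
                          stress_bursts_per_day = 8,
                          eda_burst_amp = list(mean = 0.5, sd = 0.1),
                          wear_gap_fraction = 0.42,
                          hr_baseline = list(mean = 70, sd = 5,
                                             bout_delta = 25, noise_sd = 3),
                          rates = c(HR = 1, EDA = 4, TEMP = 4, ACC = 32),
                          tz_offset = 0) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 2) abort("config error: n_participants must be >= 2")
  all_days <- if (is.null(cfg$days)) cfg$days_range else cfg$days
  if (any(all_days < 2)) {
    abort("config error: days must be >= 2 (the 24-h rolling window needs history)")
  }
  nonneg <- c(cfg$circadian_amp, cfg$meal_response$peak_per_g_sugar,
              cfg$meal_response$peak_per_g_carb, cfg$activity_dip$drop_mg_dl,
              cfg$noise$sd, cfg$meals_per_day, cfg$bouts_per_day,
              cfg$stress_bursts_per_day, cfg$wear_gap_fraction)
  if (any(nonneg < 0)) abort("config error: rates and amplitudes must be >= 0")
  if (any(cfg$rates <= 0)) abort("config error: sampling rates must be positive")
  invisible(cfg)
}

# First UTC-midnight anchor used for all synthetic cohorts.
SYNTH_T0 <- 1600041600

#' Generate a synthetic cohort
#'
#' Produces one [participant_record()] per participant. Glucose is built as
#' baseline + circadian sinusoid + sum of meal-response kernels + sum of
#' activity-dip kernels + AR(1) noise, clipped to 40-300 mg/dL. Heart rate
#' and accelerometry are elevated during planted activity bouts, the EDA
#' trace carries planted peak bursts, and the IBI list is derived from heart
#' rate with multiplicative jitter so HRV features are non-degenerate.
#' Deterministic given `config$seed`; each participant draws from an
#' independent substream keyed by a fixed per-participant offset, so records
#' are reproducible under cohort-size changes.
#'
#' @param config A [cohort_config()].
#' @return List of [participant_record()]s; each carries its planted-truth
#'   event table (see [planted_truth()]) as an attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  lapply(seq_len(config$n_participants), function(i) {
    generate_participant(config, i)
  })
}

participant_seed <- function(seed, i) (as.integer(seed) %% 100000L) * 10000L + i

generate_participant <- function(cfg, i) {
  set.seed(participant_seed(cfg$seed, i))
  days <- if (is.null(cfg$days)) {
    sample(seq(cfg$days_range[1], cfg$days_range[2]), 1)
  } else if (length(cfg$days) == 1) cfg$days else cfg$days[i]
  days <- as.integer(days)
  t0 <- SYNTH_T0
  span <- days * 86400
  n_epochs <- days * EPOCHS_PER_DAY
  grid <- t0 + (seq_len(n_epochs) - 1) * EPOCH_SECONDS

  # --- planted events -------------------------------------------------
  meals <- plant_meals(cfg, t0, days)
  bouts <- plant_bouts(cfg, t0, days)
  bursts_t <- t0 + sort(unlist(lapply(seq_len(days) - 1, function(d) {
    n <- rpois(1, cfg$stress_bursts_per_day)
    d * 86400 + runif(n, 0, 86400)
  })))

  # --- glucose ---------------------------------------------------------
  baseline <- rnorm(1, cfg$glucose_baseline$mean, cfg$glucose_baseline$sd)
  hours_local <- ((grid + cfg$tz_offset) %% 86400) / 3600
  circ <- cfg$circadian_amp * cos(2 * pi * (hours_local - cfg$circadian_peak_hour) / 24)
  meal_fx <- meal_effect(grid, meals, cfg$meal_response)
  dip_fx <- activity_effect(grid, bouts, cfg$activity_dip)
  eps <- if (cfg$noise$sd > 0) {
    as.numeric(stats::filter(rnorm(n_epochs, 0, cfg$noise$sd),
                             cfg$noise$ar1, method = "recursive"))
  } else rep(0, n_epochs)
  glucose_vals <- pmin(300, pmax(40, baseline + circ + meal_fx + dip_fx + eps))
  keep <- if (cfg$wear_gap_fraction > 0) {
    runif(n_epochs) >= cfg$wear_gap_fraction
  } else rep(TRUE, n_epochs)
  glucose <- tibble::tibble(time = grid[keep], glucose_mg_dl = glucose_vals[keep])

  # --- wearable streams ------------------------------------------------
  in_bout <- function(tt) {
    out <- rep(FALSE, length(tt))
    for (k in seq_len(nrow(bouts))) {
      out <- out | (tt >= bouts$start[k] & tt < bouts$end[k])
    }
    out
  }
  hr_base <- rnorm(1, cfg$hr_baseline$mean, cfg$hr_baseline$sd)
  n_hr <- span * cfg$rates[["HR"]]
  t_hr <- t0 + (seq_len(n_hr) - 1) / cfg$rates[["HR"]]
  hr_circ <- -4 * cos(2 * pi * (((t_hr + cfg$tz_offset) %% 86400) / 3600 - 16) / 24)
  hr_vals <- hr_base + hr_circ + cfg$hr_baseline$bout_delta * in_bout(t_hr) +
    rnorm(n_hr, 0, cfg$hr_baseline$noise_sd)
  hr_vals <- pmax(35, hr_vals)
  hr <- sensor_stream("HR", t0, cfg$rates[["HR"]], hr_vals)

  acc <- generate_acc(cfg, t0, span, bouts)
  temp <- generate_temp(cfg, t0, span)
  eda <- generate_eda(cfg, t0, span, bursts_t)
  ibi <- generate_ibi(hr_vals, cfg$rates[["HR"]], t0)

  truth <- dplyr::bind_rows(
    tibble::tibble(kind = "meal", start = meals$time, end = meals$time + 7200),
    tibble::tibble(kind = "bout", start = bouts$start, end = bouts$end),
    tibble::tibble(kind = "stress", start = bursts_t, end = bursts_t + 60)
  )
  truth$participant_id <- i
  truth <- truth[, c("participant_id", "kind", "start", "end")]

  p <- participant_record(
    participant_id = i,
    sex = rbinom(1, 1, 0.5),
    hba1c = round(runif(1, 5.2, 6.4), 1),
    streams = list(HR = hr, EDA = eda, TEMP = temp, ACC = acc),
    ibi = ibi, glucose = glucose,
    food = meals[, c("time", "calories_kcal", "protein_g", "carbs_g",
                     "sugar_g", "label")]
  )
  attr(p, "truth") <- truth
  p
}

plant_meals <- function(cfg, t0, days) {
  if (cfg$meals_per_day == 0) {
    return(tibble::tibble(time = numeric(0), calories_kcal = numeric(0),
                          protein_g = numeric(0), carbs_g = numeric(0),
                          sugar_g = numeric(0), label = character(0)))
  }
  rows <- lapply(seq_len(days) - 1, function(d) {
    n <- max(1L, rpois(1, cfg$meals_per_day))
    tt <- sort(runif(n, 6.5 * 3600, 21 * 3600))
    tibble::tibble(
      time = t0 + d * 86400 + tt,
      calories_kcal = round(runif(n, 150, 800)),
      protein_g = round(runif(n, 5, 40)),
      carbs_g = round(runif(n, 20, 100)),
      sugar_g = round(runif(n, 5, 50)),
      label = sprintf("meal_d%d_%d", d + 1, seq_len(n))
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$time)
}

plant_bouts <- function(cfg, t0, days) {
  if (cfg$bouts_per_day == 0) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  rows <- lapply(seq_len(days) - 1, function(d) {
    n <- cfg$bouts_per_day
    sod <- sort(runif(n, 8 * 3600, 20 * 3600))
    dur <- runif(n, cfg$bout_duration_min[1], cfg$bout_duration_min[2]) * 60
    tibble::tibble(start = t0 + d * 86400 + sod,
                   end = t0 + d * 86400 + sod + dur)
  })
  dplyr::bind_rows(rows)
}

# Log-normal-shaped meal impulse, peak scaled to the per-gram response.
meal_effect <- function(grid, meals, mr) {
  fx <- rep(0, length(grid))
  if (!nrow(meals) || (mr$peak_per_g_sugar == 0 && mr$peak_per_g_carb == 0)) {
    return(fx)
  }
  sdlog <- 0.5
  meanlog <- log(mr$lag_min) + sdlog^2   # mode at lag_min
  peak_dens <- dlnorm(mr$lag_min, meanlog, sdlog)
  horizon <- (mr$lag_min + 6 * mr$decay_min) * 60
  for (k in seq_len(nrow(meals))) {
    amp <- mr$peak_per_g_sugar * meals$sugar_g[k] +
      mr$peak_per_g_carb * meals$carbs_g[k]
    tau <- grid - meals$time[k]
    sel <- tau > 0 & tau <= horizon
    if (any(sel)) {
      fx[sel] <- fx[sel] + amp * dlnorm(tau[sel] / 60, meanlog, sdlog) / peak_dens
    }
  }
  fx
}

# Rectangular drop during the bout plus exponential recovery afterwards.
activity_effect <- function(grid, bouts, ad) {
  fx <- rep(0, length(grid))
  if (!nrow(bouts) || ad$drop_mg_dl == 0) return(fx)
  lag <- ad$lag_min * 60
  tau_rec <- ad$recovery_min * 60
  for (k in seq_len(nrow(bouts))) {
    s <- bouts$start[k] + lag
    e <- bouts$end[k]
    during <- grid >= s & grid < e
    after <- grid >= e & grid < e + 6 * tau_rec
    fx[during] <- fx[during] - ad$drop_mg_dl
    fx[after] <- fx[after] - ad$drop_mg_dl * exp(-(grid[after] - e) / tau_rec)
  }
  fx
}

generate_acc <- function(cfg, t0, span, bouts) {
  rate <- cfg$rates[["ACC"]]
  n <- span * rate
  # integer 1/64 g counts, as the device exports; wrist at rest reads ~1 g on z
  x <- as.integer(round(rnorm(n, 0, 3)))
  y <- as.integer(round(rnorm(n, 0, 3)))
  z <- as.integer(round(rnorm(n, 64, 3)))
  for (k in seq_len(nrow(bouts))) {
    i0 <- max(1L, as.integer(floor((bouts$start[k] - t0) * rate)) + 1L)
    i1 <- min(n, as.integer(ceiling((bouts$end[k] - t0) * rate)))
    if (i1 >= i0) {
      m <- i1 - i0 + 1L
      x[i0:i1] <- x[i0:i1] + as.integer(round(rnorm(m, 20, 15)))
      y[i0:i1] <- y[i0:i1] + as.integer(round(rnorm(m, 20, 15)))
    }
  }
  sensor_stream("ACC", t0, rate, cbind(x, y, z))
}

generate_temp <- function(cfg, t0, span) {
  rate <- cfg$rates[["TEMP"]]
  n <- span * rate
  tt <- t0 + (seq_len(n) - 1) / rate
  vals <- 33 + 0.5 * cos(2 * pi * (((tt + cfg$tz_offset) %% 86400) / 3600 - 16) / 24) +
    rnorm(n, 0, 0.05)
  sensor_stream("TEMP", t0, rate, vals)
}

generate_eda <- function(cfg, t0, span, bursts_t) {
  rate <- cfg$rates[["EDA"]]
  n <- span * rate
  tt_day <- (t0 + (seq_len(n) - 1) / rate) %% 86400
  vals <- 0.3 + 0.1 * sin(2 * pi * tt_day / 86400) + rnorm(n, 0, 0.005)
  if (length(bursts_t)) {
    # skin-conductance-response shape: 1-s linear rise, 8-s exponential decay
    rise <- seq(0, 1, length.out = rate + 1)[-1]
    decay <- exp(-seq_len(8 * rate) / (2 * rate))
    kern <- c(rise, decay)
    for (bt in bursts_t) {
      n_peaks <- rpois(1, 2) + 1L
      gaps <- cumsum(c(0, runif(n_peaks - 1, 5, 10)))
      for (g in gaps) {
        amp <- max(0.35, rnorm(1, cfg$eda_burst_amp$mean, cfg$eda_burst_amp$sd))
        i0 <- as.integer(floor((bt + g - t0) * rate)) + 1L
        idx <- i0:(i0 + length(kern) - 1L)
        ok <- idx >= 1L & idx <= n
        vals[idx[ok]] <- vals[idx[ok]] + amp * kern[ok]
      }
    }
  }
  sensor_stream("EDA", t0, rate, pmax(0.01, vals))
}

# Beats paced by the 1-Hz heart-rate trace with multiplicative jitter, so
# interval statistics (SDNN/RMSSD/...) are non-degenerate.
generate_ibi <- function(hr_vals, hr_rate, t0) {
  epoch_len <- EPOCH_SECONDS
  n_epochs <- as.integer(floor(length(hr_vals) / (hr_rate * epoch_len)))
  offs <- vector("list", n_epochs)
  ints <- vector("list", n_epochs)
  for (j in seq_len(n_epochs)) {
    i0 <- as.integer((j - 1) * hr_rate * epoch_len) + 1L
    h <- mean(hr_vals[i0:(i0 + as.integer(hr_rate * epoch_len) - 1L)])
    base_int <- 60 / h
    k <- as.integer(floor(epoch_len / base_int)) - 1L
    if (k < 1) next
    iv <- pmax(0.3, base_int * (1 + rnorm(k, 0, 0.04)))
    o <- (j - 1) * epoch_len + cumsum(iv)
    keep <- o < (j - 1) * epoch_len + epoch_len
    offs[[j]] <- o[keep]
    ints[[j]] <- iv[keep]
  }
  out <- tibble::tibble(offset_s = unlist(offs), interval_s = unlist(ints))
  attr(out, "start_time") <- t0
  out
}

#' Planted ground-truth event windows of a synthetic cohort
#'
#' Returns the meal, activity-bout and stress-burst windows the generator
#' planted, for validating downstream detectors (e.g. that detected activity
#' bouts overlap planted bouts).
#'
#' @param cohort A list of participants from [generate_cohort()].
#' @return A tibble with columns `participant_id`, `kind`
#'   (`"meal"`/`"bout"`/`"stress"`), `start`, `end`.
#' @export
planted_truth <- function(cohort) {
  truths <- lapply(cohort, attr, "truth")
  if (any(vapply(truths, is.null, logical(1)))) {
    abort("cohort was not produced by generate_cohort(): no planted truth")
  }
  dplyr::bind_rows(truths)
}
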
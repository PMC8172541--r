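test_that("prior-window rollups match the brute-force oracle", {
  set.seed(404)
  for (rep in 1:100) {
    n <- sample(5:80, 1)
    x <- rnorm(n)
    x[sample(n, floor(n / 6))] <- NA
    w <- sample(2:30, 1)
    expect_identical(glucowear:::roll_prior(x, w, "sum"),
                     oracle_roll_prior(x, w, sum))
    expect_identical(glucowear:::roll_prior(x, w, "mean"),
                     oracle_roll_prior(x, w, mean))
    expect_identical(glucowear:::roll_prior(x, w, "max"),
                     oracle_roll_prior(x, w, max))
  }
})

test_that("EDA peak rollups sum and average the previous 2 h of epochs", {
  zero <- rep(0, 40)
  expect_equal(glucowear:::roll_prior(zero, 24, "sum", empty = 0)[30], 0)
  expect_equal(glucowear:::roll_prior(zero, 24, "mean", empty = 0)[30], 0)
  twos <- rep(2, 40)
  expect_equal(glucowear:::roll_prior(twos, 24, "sum", empty = 0)[25], 48)
  expect_equal(glucowear:::roll_prior(twos, 24, "mean", empty = 0)[25], 2)
})

test_that("activity rollups cover 1-h sums and 24-h means", {
  bouts <- rep(0, 400)
  bouts[100:111] <- 1 # 12 consecutive bout epochs
  s1h <- glucowear:::roll_prior(bouts, 12, "sum", empty = 0)
  expect_equal(s1h[112], 12)
  expect_equal(s1h[118], 6)
  m24 <- glucowear:::roll_prior(bouts, 288, "mean", empty = 0)
  expect_equal(m24[380], 12 / 288)  # window 92:379 holds all 12 bout epochs
  expect_equal(m24[400], 0)         # window 112:399 holds none

})

test_that("food features respect half-open historical windows", {
  t <- 1600041600 + 86400
  food <- tibble::tibble(
    time = c(t - 3600, t - 10 * 3600),
    calories_kcal = c(400, 250), protein_g = c(20, 10),
    carbs_g = c(50, 30), sugar_g = c(30, 20),
    label = c("a", "b")
  )
  f <- food_features(food, t)
  expect_equal(f$sugar_2h, 30)
  expect_equal(f$sugar_8h, 30)
  expect_equal(f$sugar_24h, 50)
  expect_equal(f$eating_count_2h, 1)
  expect_equal(f$eating_count_24h, 2)
  expect_equal(f$eating_mean_2h, 1 / 24)
  expect_equal(f$eating_mean_24h, 2 / 288)
  expect_equal(f$eating_event, 0)

  # an event inside the most recent epoch flips the binary
  f2 <- food_features(dplyr::mutate(food, time = c(t - 100, t - 10 * 3600)), t)
  expect_equal(f2$eating_event, 1)
  # an event exactly at t is future data and never counted
  f3 <- food_features(dplyr::mutate(food, time = c(t, t - 10 * 3600)), t)
  expect_equal(f3$eating_event, 0)
  expect_equal(f3$sugar_24h, 20)

  empty <- food[0, ]
  fe <- food_features(empty, t)
  expect_true(all(as.numeric(fe[1, ]) == 0))
  expect_equal(ncol(fe), 19)
})

test_that("random food logs match the brute-force oracle", {
  set.seed(505)
  t0 <- 1600041600
  for (rep in 1:60) {
    m <- sample(1:40, 1)
    food <- tibble::tibble(
      time = sort(t0 + runif(m, 0, 3 * 86400)),
      calories_kcal = runif(m, 50, 900), protein_g = runif(m, 0, 50),
      carbs_g = runif(m, 0, 120), sugar_g = runif(m, 0, 60),
      label = rep("x", m)
    )
    targets <- t0 + 86400 + runif(4, 0, 86400)
    f <- food_features(food, targets)
    for (i in seq_along(targets)) {
      for (w in c(2, 8, 24)) {
        expect_equal(f[[paste0("sugar_", w, "h")]][i],
                     oracle_food_sum(food$time, food$sugar_g, targets[i], w * 3600))
        expect_equal(f[[paste0("calories_", w, "h")]][i],
                     oracle_food_sum(food$time, food$calories_kcal, targets[i], w * 3600))
        cnt <- sum(food$time >= targets[i] - w * 3600 & food$time < targets[i])
        expect_equal(f[[paste0("eating_count_", w, "h")]][i], cnt)
        expect_equal(f[[paste0("eating_mean_", w, "h")]][i], cnt / (w * 12))
      }
    }
  }
})

test_that("wake time is found on a square-wave day and skipped on flat days", {
  t0 <- 1600041600
  n <- 2 * 288
  step_at <- 96 # epoch index of 08:00 within each day
  level <- rep(c(rep(1, step_at), rep(3, 288 - step_at)), 2)
  epochs <- tibble::tibble(
    epoch_start = t0 + (seq_len(n) - 1) * 300,
    acc_mean = level, acc_sd = level, hr_mean = level, hr_sd = level
  )
  wk <- detect_wake_times(epochs)
  expect_equal(nrow(wk), 2)
  expect_true(all(abs(wk$wake_minutes - 480) <= 15))

  flat <- dplyr::mutate(epochs, acc_mean = 1, acc_sd = 1, hr_mean = 1, hr_sd = 1)
  expect_true(all(is.na(detect_wake_times(flat)$wake_minutes)))
})

test_that("assembled tables have the 69-column schema and full-day burn-in", {
  p <- manual_participant(days = 3)
  tbl <- assemble_features(p)
  expect_equal(names(tbl), c("participant_id", "epoch_start",
                             feature_schema(), "glucose_target"))
  expect_length(feature_schema(), 69)
  # first 24 h dropped: 2 x 288 rows remain for a gap-free 3-day wear
  expect_equal(nrow(tbl), 2 * 288)
  expect_true(all(tbl$epoch_start >= min(p$glucose$time) + 86400))
  # constant sensors: flat statistics, zero peaks, defined skews
  expect_true(all(tbl$hr_mean == 70))
  expect_true(all(tbl$hr_skew == 0))
  expect_true(all(tbl$eda_peaks == 0))
  expect_true(all(tbl$pnn50 == 0))
  expect_true(all(tbl$personalization == 1))
  # participants with under a day of data yield an empty table with warning
  short <- manual_participant(days = 2)
  short$glucose <- short$glucose[1:100, ]
  expect_warning(empty <- assemble_features(short), "24 h")
  expect_equal(nrow(empty), 0)
})

test_that("wake feature carries the previous day's detected wake", {
  t0 <- 1600041600
  days <- 3
  span <- days * 86400
  # HR and ACC step up at 07:00 every day
  mk_step <- function(rate, low, high) {
    tt <- t0 + (seq_len(span * rate) - 1) / rate
    sod <- tt %% 86400
    ifelse(sod >= 7 * 3600, high, low) + sin(tt / 977) * 0.2
  }
  p <- manual_participant(days = days)
  p$streams$HR <- sensor_stream("HR", t0, 1, mk_step(1, 55, 80))
  acc_vals <- mk_step(4, 10, 60)
  p$streams$ACC <- sensor_stream("ACC", t0, 4, cbind(0, 0, acc_vals))
  tbl <- assemble_features(p)
  # rows exist only on days 2..3; each carries the prior day's wake near 420 min
  expect_true(all(abs(tbl$wake_time - 420) <= 30))
})
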
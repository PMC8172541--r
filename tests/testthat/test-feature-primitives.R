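test_that("vector magnitude follows the 1/64 g convention", {
  expect_equal(vector_magnitude(0, 0, 0), 0)
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(64, 0, 0), 64) # exactly 1 g
  expect_equal(vector_magnitude(c(3, 64), c(4, 0), c(0, 0)), c(5, 64))
})

test_that("summary statistics match definitions and a brute-force oracle", {
  s <- summary_stats(rep(5, 10), prefix = "x")
  expect_equal(unname(s), c(5, 0, 5, 5, 5, 5, 0))
  expect_named(s, paste0("x_", c("mean", "sd", "min", "max", "q1", "q3", "skew")))

  s <- summary_stats(c(1, 2, 3, 4))
  expect_equal(unname(s[c("mean", "min", "max")]), c(2.5, 1, 4))

  expect_true(all(is.na(summary_stats(3.2))))
  expect_true(all(is.na(summary_stats(numeric(0)))))

  set.seed(101)
  for (rep in 1:100) {
    x <- rnorm(300, 70, 8)
    s <- summary_stats(x)
    expect_equal(unname(s["mean"]), sum(x) / length(x))
    expect_equal(unname(s["sd"]), sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
    expect_equal(unname(s["min"]), min(x))
    expect_equal(unname(s["max"]), max(x))
    xs <- sort(x)
    # linear interpolation of order statistics at p = 0.25, 0.75
    h <- 0.25 * (length(x) - 1) + 1
    expect_equal(unname(s["q1"]), xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)]))
    h <- 0.75 * (length(x) - 1) + 1
    expect_equal(unname(s["q3"]), xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)]))
    expect_equal(unname(s["skew"]), oracle_skew(x))
  }
})

test_that("EDA peak counting honors prominence and distance rules", {
  expect_equal(detect_eda_peaks(rep(0.4, 100)), 0)
  expect_equal(detect_eda_peaks(numeric(0)), 0)

  # three 0.5-uS bumps 10 s apart at 4 Hz
  x <- make_bump_signal(200, centers = c(50, 90, 130), heights = rep(0.5, 3))
  expect_equal(detect_eda_peaks(x), 3)

  # a 0.2-uS bump is below the 0.3-uS prominence threshold
  x <- make_bump_signal(100, centers = 50, heights = 0.2)
  expect_equal(detect_eda_peaks(x), 0)

  # two tall candidates 2 samples apart: only the higher survives
  x <- rep(0, 30)
  x[c(10, 12)] <- c(0.5, 0.6)
  expect_equal(detect_eda_peaks(x), 1)
  expect_equal(detect_eda_peaks(x, positions = TRUE), 12L)
})

test_that("peak counts equal the independent prominence oracle on random signals", {
  set.seed(202)
  for (rep in 1:120) {
    n <- sample(50:400, 1)
    n_bumps <- sample(0:6, 1)
    x <- make_bump_signal(
      n, centers = sort(runif(n_bumps, 5, n - 5)),
      heights = runif(n_bumps, 0.1, 0.8),
      width = runif(1, 2, 8), baseline = 0.3
    ) + cumsum(rnorm(n, 0, 0.01)) # slow drift
    expect_equal(detect_eda_peaks(x), oracle_peak_count(x),
                 info = sprintf("case %d", rep))
  }
})

test_that("HRV metrics match hand computations and the oracle", {
  m <- hrv_metrics(c(0.8, 0.8, 0.8))
  expect_equal(unname(m[c("sdnn", "rmssd", "nn50", "pnn50")]), c(0, 0, 0, 0))
  expect_equal(unname(m["ibi_mean"]), 800)

  # [700, 760] ms: one successive difference of 60 ms
  m <- hrv_metrics(c(0.7, 0.76))
  expect_equal(unname(m["rmssd"]), 60)
  expect_equal(unname(m["nn50"]), 1)
  expect_equal(unname(m["pnn50"]), 0.5) # denominator = 2 intervals

  expect_true(all(is.na(hrv_metrics(numeric(0)))))
  one <- hrv_metrics(0.8)
  expect_equal(unname(one["ibi_mean"]), 800)
  expect_true(all(is.na(one[c("sdnn", "rmssd", "nn50", "pnn50")])))

  set.seed(303)
  for (rep in 1:100) {
    iv <- runif(sample(2:40, 1), 0.5, 1.2)
    got <- hrv_metrics(iv)
    want <- oracle_hrv(iv)
    for (k in names(want)) {
      expect_equal(unname(got[k]), want[[k]], info = k)
    }
    expect_gte(got[["pnn50"]], 0)
    expect_lte(got[["pnn50"]], 1)
  }
})

test_that("circadian features convert clock time", {
  midnight <- 1600041600 # a UTC midnight
  cf <- circadian_features(midnight)
  expect_equal(cf$minutes_from_midnight, 0)
  expect_equal(cf$hours_from_midnight, 0)
  cf <- circadian_features(midnight + 90 * 60)
  expect_equal(cf$minutes_from_midnight, 90)
  expect_equal(cf$hours_from_midnight, 1.5)
  cf <- circadian_features(midnight + 1435 * 60)
  expect_equal(cf$minutes_from_midnight, 1435)
  expect_equal(cf$hours_from_midnight, 1435 / 60)
  # timezone offset shifts the wall clock
  cf <- circadian_features(midnight, tz_offset = -3600)
  expect_equal(cf$minutes_from_midnight, 1380)
})

test_that("activity bout requires both signals above their expanding means", {
  acc <- c(60, 60, 80, 60, 90)
  hr <- c(70, 70, 95, 98, 60)
  # epoch 3: acc 80 > mean(60,60), hr 95 > mean(70,70) -> bout
  # epoch 4: acc 60 below; epoch 5: hr below
  expect_equal(activity_bout_indicator(acc, hr), c(0L, 0L, 1L, 0L, 0L))
  expect_equal(activity_bout_indicator(c(NA, 70, 80), c(70, NA, 90))[3], 1L)
  expect_equal(activity_bout_indicator(numeric(0), numeric(0)), integer(0))
})
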
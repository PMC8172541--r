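fast_rates <- c(HR = 1, EDA = 2, TEMP = 1, ACC = 2)

test_that("gap-free cohorts have 288 glucose epochs per day and all parts", {
  cfg <- cohort_config(n_participants = 2, days = 2, seed = 3,
                       rates = fast_rates, wear_gap_fraction = 0)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 2)
  for (p in cohort) {
    expect_equal(nrow(p$glucose), 2 * 288)
    expect_setequal(names(p$streams), c("HR", "EDA", "TEMP", "ACC"))
    expect_gt(nrow(p$ibi), 0)
    expect_gt(nrow(p$food), 0)
    expect_true(all(p$glucose$glucose_mg_dl >= 40 & p$glucose$glucose_mg_dl <= 300))
    expect_true(all(is.finite(p$glucose$glucose_mg_dl)))
    expect_true(p$hba1c >= 5.2 && p$hba1c <= 6.4)
    expect_true(p$sex %in% c(0, 1))
    # streams span the glucose window
    expect_lte(p$streams$HR$time[1], p$glucose$time[1])
    expect_gte(max(p$streams$HR$time), max(p$glucose$time) - 300)
  }
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_participants = 2, days = 2, seed = 11, rates = fast_rates)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a[[1]]$glucose, b[[1]]$glucose)
  expect_identical(as.data.frame(a[[2]]$streams$EDA), as.data.frame(b[[2]]$streams$EDA))
  expect_identical(a[[1]]$food, b[[1]]$food)
  expect_identical(planted_truth(a), planted_truth(b))
})

test_that("with effects and noise off, glucose is exactly baseline + sinusoid", {
  cfg <- cohort_config(
    n_participants = 2, days = 2, seed = 5, rates = fast_rates,
    meal_response = list(peak_per_g_sugar = 0, peak_per_g_carb = 0,
                         lag_min = 30, decay_min = 90),
    activity_dip = list(drop_mg_dl = 0, lag_min = 5, recovery_min = 30),
    noise = list(ar1 = 0.7, sd = 0), wear_gap_fraction = 0,
    circadian_amp = 8, circadian_peak_hour = 16
  )
  p <- generate_cohort(cfg)[[1]]
  t <- p$glucose$time
  hours <- (t %% 86400) / 3600
  X <- cbind(1, cos(2 * pi * hours / 24), sin(2 * pi * hours / 24))
  fit <- lm.fit(X, p$glucose$glucose_mg_dl)
  amp_hat <- sqrt(fit$coefficients[2]^2 + fit$coefficients[3]^2)
  phase_hat <- atan2(fit$coefficients[3], fit$coefficients[2]) / (2 * pi) * 24
  expect_equal(unname(amp_hat), 8, tolerance = 1e-6)
  expect_equal(unname(phase_hat %% 24), 16, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("planted truth reflects the configured event bookkeeping", {
  cfg <- cohort_config(n_participants = 2, days = 2, seed = 9,
                       rates = fast_rates, bouts_per_day = 3, meals_per_day = 0)
  truth <- planted_truth(generate_cohort(cfg))
  expect_equal(sum(truth$kind == "meal"), 0)
  expect_equal(sum(truth$kind == "bout" & truth$participant_id == 1), 6)
  expect_true(all(truth$end >= truth$start))
  expect_error(planted_truth(list(manual_participant())), "planted truth")
})

test_that("doubling the sugar response strictly raises post-meal 2-h AUC", {
  base_args <- list(
    n_participants = 2, days = 2, seed = 21, rates = fast_rates,
    activity_dip = list(drop_mg_dl = 0, lag_min = 5, recovery_min = 30),
    noise = list(ar1 = 0, sd = 0), wear_gap_fraction = 0
  )
  mk <- function(sugar_amp) {
    cfg <- do.call(cohort_config, c(base_args, list(
      meal_response = list(peak_per_g_sugar = sugar_amp, peak_per_g_carb = 0.3,
                           lag_min = 30, decay_min = 90)
    )))
    generate_cohort(cfg)
  }
  low <- mk(0.4)
  high <- mk(0.8)
  auc_after_meals <- function(cohort) {
    truth <- planted_truth(cohort)
    meals <- truth[truth$kind == "meal" & truth$participant_id == 1, ]
    g <- cohort[[1]]$glucose
    sum(vapply(meals$start, function(m) {
      sum(g$glucose_mg_dl[g$time > m & g$time <= m + 7200])
    }, numeric(1)))
  }
  expect_gt(auc_after_meals(high), auc_after_meals(low))
})

test_that("default wear-gap fraction yields roughly 1500 glucose points over 9 days", {
  cfg <- cohort_config(n_participants = 2, days = 9, seed = 13,
                       rates = c(HR = 1, EDA = 1, TEMP = 1, ACC = 1))
  cohort <- generate_cohort(cfg)
  counts <- vapply(cohort, function(p) nrow(p$glucose), numeric(1))
  expect_true(all(abs(counts - 1500) < 120))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_participants = 1), "n_participants")
  expect_error(cohort_config(days = 1), "days")
  expect_error(cohort_config(circadian_amp = -1), "amplitudes")
})
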
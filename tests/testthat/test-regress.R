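test_that("error metrics match their closed forms", {
  expect_equal(rmse(c(100, 100), c(90, 110)), 10)
  expect_equal(mape(c(100, 100), c(90, 110)), 10)
  expect_equal(accuracy_from_mape(10), 90)
  y <- c(95, 120, 140)
  expect_equal(rmse(y, y), 0)
  expect_equal(mape(y, y), 0)
  expect_equal(accuracy_from_mape(mape(y, y)), 100)
  set.seed(3)
  for (rep in 1:50) {
    y <- runif(30, 60, 200)
    yh <- y + rnorm(30, 0, 15)
    expect_equal(rmse(y, yh), sqrt(sum((y - yh)^2) / 30))
    expect_equal(mape(y, yh), 100 * sum(abs(y - yh) / y) / 30)
  }
  expect_error(mape(c(100, 0), c(90, 10)), "undefined")
})

test_that("naive baselines predict the train mean or median", {
  out <- naive_baselines(c(100, 110, 120), 110)
  expect_equal(out$rmse[out$baseline == "mean"], 0)
  expect_equal(out$accuracy[out$baseline == "mean"], 100)
  skewed <- c(100, 100, 100, 200)
  out <- naive_baselines(skewed, c(100, 100))
  expect_equal(out$rmse[out$baseline == "median"], 0)      # median = 100
  expect_equal(out$rmse[out$baseline == "mean"], 25)       # mean = 125
  expect_equal(out$accuracy, 100 - out$mape)
})

test_that("LOPOCV has one fold per participant and learns planted structure", {
  feats <- make_reg_features(n_participants = 3, rows_per = 100)
  rep_gbt <- fit_predict_lopocv(feats, fast_reg_config())
  expect_equal(nrow(rep_gbt$per_fold), 3)
  expect_equal(sort(rep_gbt$per_fold$participant_id), 1:3)
  expect_true(all(is.finite(rep_gbt$predictions$predicted)))
  expect_equal(rep_gbt$per_fold$accuracy, 100 - rep_gbt$per_fold$mape)
  # selected features are a subset of the schema; importances sum to 1
  for (sel in rep_gbt$selected_features) {
    expect_true(all(sel %in% feature_schema()))
  }
  for (imp in rep_gbt$importances) {
    expect_equal(sum(imp), 1)
  }
  # planted signal beats both naive baselines
  rep_mean <- fit_predict_lopocv(feats, fast_reg_config(), model = "naive_mean")
  rep_med <- fit_predict_lopocv(feats, fast_reg_config(), model = "naive_median")
  expect_lt(mean(rep_gbt$per_fold$mape), mean(rep_mean$per_fold$mape))
  expect_lt(mean(rep_gbt$per_fold$mape), mean(rep_med$per_fold$mape))
  expect_s3_class(glance(rep_gbt), "tbl_df")
  expect_s3_class(autoplot(rep_gbt), "ggplot")
})

test_that("LOPOCV folds never see the held-out participant", {
  feats <- make_reg_features(n_participants = 3, rows_per = 80, seed = 9)
  cfg <- fast_reg_config()
  ref <- fit_predict_lopocv(feats, cfg)
  poisoned <- feats
  rows1 <- poisoned$participant_id == 1
  poisoned$glucose_target[rows1] <- 9999 # sentinel targets for fold 1's test set
  poi <- fit_predict_lopocv(poisoned, cfg)
  p_ref <- ref$predictions[ref$predictions$participant_id == 1, ]
  p_poi <- poi$predictions[poi$predictions$participant_id == 1, ]
  expect_identical(p_ref$predicted, p_poi$predicted)
  expect_identical(ref$selected_features[["1"]], poi$selected_features[["1"]])
})

test_that("the personalized split is chronological and learns constants", {
  feats <- make_reg_features(n_participants = 2, rows_per = 100, seed = 5,
                             target_fun = function(d) rep(120, nrow(d)))
  rep_p <- fit_predict_personalized(feats, fast_reg_config())
  expect_equal(nrow(rep_p$per_fold), 2)
  expect_lt(max(rep_p$per_fold$rmse), 1) # constant target is learnable
  # each participant's test rows all come after their train rows
  for (pid in 1:2) {
    pr <- rep_p$predictions[rep_p$predictions$participant_id == pid, ]
    rows <- feats[feats$participant_id == pid, ]
    split_at <- ceiling(nrow(rows) / 2)
    expect_equal(nrow(pr), nrow(rows) - split_at)
    expect_true(min(pr$epoch_start) > sort(rows$epoch_start)[split_at])
  }
  expect_error(
    fit_predict_personalized(make_reg_features(rows_per = 10), fast_reg_config()),
    "too few"
  )
})

test_that("prediction clipping is off by default and honored when set", {
  feats <- make_reg_features(n_participants = 2, rows_per = 60, seed = 11)
  clipped <- regressor_config(fs = list(rf_trees = 40, importance_cutoff = 0.005),
                              clip = c(40, 400))
  rep_c <- fit_predict_lopocv(feats, clipped)
  expect_true(all(rep_c$predictions$predicted >= 40 &
                    rep_c$predictions$predicted <= 400))
})
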
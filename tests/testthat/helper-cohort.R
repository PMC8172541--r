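# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small cohort at reduced ACC rate: fast, still exercises every code path.
small_cohort <- function() {
  cached("small_cohort", generate_cohort(cohort_config(
    n_participants = 3, days = 3, seed = 42,
    rates = c(HR = 1, EDA = 4, TEMP = 2, ACC = 4),
    wear_gap_fraction = 0.05
  )))
}

small_features <- function() {
  cached("small_features", cohort_features(small_cohort()))
}

# Hand-built participant: every stream constant except where a test injects
# structure; keeps arithmetic transparent for oracle comparisons.
manual_participant <- function(id = 1, days = 2, t0 = 1600041600,
                               hr = 70, eda = 0.4, temp = 33, acc_z = 64,
                               glucose_fun = function(t) rep(100, length(t)),
                               food = NULL,
                               rates = c(HR = 1, EDA = 4, TEMP = 2, ACC = 4)) {
  span <- days * 86400
  n_ep <- days * 288
  grid <- t0 + (seq_len(n_ep) - 1) * 300
  mk <- function(kind, rate, value) {
    n <- span * rate
    vals <- if (length(value) == 1) rep(value, n) else value
    if (kind == "ACC") {
      sensor_stream("ACC", t0, rate, cbind(0, 0, vals))
    } else {
      sensor_stream(kind, t0, rate, vals)
    }
  }
  n_beats <- floor(span / (60 / hr)) - 1
  ibi <- tibble::tibble(offset_s = cumsum(rep(60 / hr, n_beats)),
                        interval_s = rep(60 / hr, n_beats))
  attr(ibi, "start_time") <- t0
  if (is.null(food)) {
    food <- tibble::tibble(time = numeric(0), calories_kcal = numeric(0),
                           protein_g = numeric(0), carbs_g = numeric(0),
                           sugar_g = numeric(0), label = character(0))
  }
  participant_record(
    participant_id = id, sex = 0, hba1c = 5.5,
    streams = list(
      HR = mk("HR", rates[["HR"]], hr),
      EDA = mk("EDA", rates[["EDA"]], eda),
      TEMP = mk("TEMP", rates[["TEMP"]], temp),
      ACC = mk("ACC", rates[["ACC"]], acc_z)
    ),
    ibi = ibi,
    glucose = tibble::tibble(time = grid, glucose_mg_dl = glucose_fun(grid)),
    food = food
  )
}

# balanced three-class dataset with label-independent noise features
noise_classif_data <- function(n_per_class = 120, seed = 7) {
  set.seed(seed)
  n <- 3 * n_per_class
  x <- matrix(rnorm(n * 69), nrow = n,
              dimnames = list(NULL, feature_schema()))
  df <- tibble::as_tibble(x)
  df$excursion_label <- factor(rep(excursion_levels(), each = n_per_class),
                               levels = excursion_levels())
  df
}

# perfectly separable dataset: one feature encodes the class
separable_classif_data <- function(n_per_class = 60, seed = 8) {
  df <- noise_classif_data(n_per_class, seed)
  codes <- rep(c(-5, 0, 5), each = n_per_class)
  df$sugar_24h <- codes + rnorm(nrow(df), 0, 0.01)
  df
}

# feature table with a known linear signal in a couple of columns
make_reg_features <- function(n_participants = 3, rows_per = 120, seed = 1,
                              noise_sd = 2, target_fun = NULL) {
  set.seed(seed)
  n <- n_participants * rows_per
  x <- matrix(rnorm(n * 69), nrow = n,
              dimnames = list(NULL, feature_schema()))
  df <- tibble::as_tibble(x)
  df$participant_id <- rep(seq_len(n_participants), each = rows_per)
  df$epoch_start <- rep(1600041600 + (seq_len(rows_per) - 1) * 300,
                        n_participants)
  if (is.null(target_fun)) {
    target_fun <- function(d) 110 + 8 * d$sugar_2h + 5 * d$acc_vm_mean_2h +
      rnorm(nrow(d), 0, noise_sd)
  }
  df$glucose_target <- target_fun(df)
  df[, c("participant_id", "epoch_start", feature_schema(), "glucose_target")]
}

fast_reg_config <- function(seed = 0) {
  regressor_config(fs = list(rf_trees = 60, importance_cutoff = 0.005),
                   seed = seed)
}

# Effect-recovery study conditions: strong planted meal/activity effects,
# low noise, full device sampling rates. Streams are dropped after feature
# assembly to keep the cached fixture light.
recovery_cohort_config <- function(seed = 1207) {
  cohort_config(
    n_participants = 4, days = 3, seed = seed,
    meal_response = list(peak_per_g_sugar = 1.0, peak_per_g_carb = 0.3,
                         lag_min = 30, decay_min = 90),
    activity_dip = list(drop_mg_dl = 25, lag_min = 5, recovery_min = 45),
    bouts_per_day = 4, bout_duration_min = c(30, 50),
    circadian_amp = 10,
    noise = list(ar1 = 0.5, sd = 1),
    wear_gap_fraction = 0.3
  )
}

recovery_setup <- function() {
  cached("recovery_setup", {
    cohort <- generate_cohort(recovery_cohort_config())
    features <- cohort_features(cohort)
    labels <- cohort_labels(cohort)
    out <- list(
      features = features,
      labels = labels,
      labeled_features = join_labels(features, labels),
      truth = planted_truth(cohort)
    )
    rm(cohort); gc()
    out
  })
}
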
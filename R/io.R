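#' Sensor stream objects
#'
#' A sensor stream is a tibble of uniformly sampled values from one
#' wrist-wearable channel, carrying its kind, absolute start time (UTC epoch
#' seconds) and sampling rate as attributes. Sample `i` (1-based) is taken at
#' `start_time + (i - 1) / rate_hz`. Accelerometry (`ACC`) carries three
#' channels `x`, `y`, `z` in units of 1/64 g; the other kinds carry a single
#' `value` column (HR in beats/min, EDA in micro-siemens, TEMP in degrees C).
#'
#' @param kind One of `"HR"`, `"EDA"`, `"TEMP"`, `"ACC"`.
#' @param start_time Absolute start time, UTC epoch seconds.
#' @param rate_hz Sampling rate in Hz (device rates: HR 1, EDA 4, TEMP 4,
#'   ACC 32).
#' @param values Numeric vector (single-channel kinds) or a 3-column
#'   matrix/data frame (`ACC`).
#' @return A tibble of class `sensor_stream` with a `time` column plus
#'   `value` or `x`/`y`/`z`.
#' @export
sensor_stream <- function(kind, start_time, rate_hz, values) {
  kind <- match.arg(kind, c("HR", "EDA", "TEMP", "ACC"))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1 || rate_hz <= 0) {
    abort("`rate_hz` must be a single positive number")
  }
  if (kind == "ACC") {
    values <- as.data.frame(values)
    if (ncol(values) != 3) {
      abort("ACC streams must have exactly 3 channels")
    }
    names(values) <- c("x", "y", "z")
    n <- nrow(values)
    out <- tibble::tibble(
      time = start_time + (seq_len(n) - 1) / rate_hz,
      x = as.numeric(values$x), y = as.numeric(values$y),
      z = as.numeric(values$z)
    )
  } else {
    values <- as.numeric(values)
    n <- length(values)
    out <- tibble::tibble(
      time = start_time + (seq_len(n) - 1) / rate_hz,
      value = values
    )
  }
  structure(out,
    class = c("sensor_stream", class(out)),
    kind = kind, start_time = start_time, rate_hz = rate_hz
  )
}

stream_kind <- function(stream) attr(stream, "kind")
stream_rate <- function(stream) attr(stream, "rate_hz")
stream_start <- function(stream) attr(stream, "start_time")

#' Read / write wearable streams in the vendor-export CSV dialect
#'
#' The on-disk dialect mirrors the study wearable's public export: line 1 is
#' the UTC epoch start time, line 2 the sample rate in Hz, and every
#' following line one sample (three comma-separated columns for ACC, where
#' the two header lines repeat the value across the columns). This layout is
#' a faithful stand-in: the source study never documents an on-disk layout.
#'
#' @param path File path.
#' @param kind Sensor kind, see [sensor_stream()].
#' @return `read_e4_stream()` returns a [sensor_stream()];
#'   `write_e4_stream()` returns `path` invisibly.
#' @export
read_e4_stream <- function(path, kind) {
  kind <- match.arg(kind, c("HR", "EDA", "TEMP", "ACC"))
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2) {
    abort(sprintf("malformed header in %s: need start-time and rate lines", path))
  }
  parse_header <- function(line, what, lineno) {
    v <- suppressWarnings(as.numeric(strsplit(line, ",", fixed = TRUE)[[1]][1]))
    if (is.na(v)) {
      abort(sprintf("malformed header in %s: line %d (%s) is not numeric",
                    path, lineno, what))
    }
    v
  }
  start_time <- parse_header(lines[1], "start time", 1L)
  rate_hz <- parse_header(lines[2], "sample rate", 2L)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  n_chan <- if (kind == "ACC") 3L else 1L
  if (length(body) == 0) {
    vals <- if (n_chan == 3L) matrix(numeric(0), ncol = 3) else numeric(0)
    return(sensor_stream(kind, start_time, rate_hz, vals))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != n_chan)
  if (length(bad)) {
    abort(sprintf("parse error in %s: row %d has %d column(s), expected %d",
                  path, bad[1], lens[bad[1]], n_chan))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(parts)),
                                  ncol = n_chan, byrow = TRUE))
  if (anyNA(vals)) {
    bad_row <- which(rowSums(is.na(vals)) > 0)[1]
    abort(sprintf("parse error in %s: non-numeric sample at data row %d",
                  path, bad_row))
  }
  sensor_stream(kind, start_time, rate_hz, if (n_chan == 1L) vals[, 1] else vals)
}

#' @rdname read_e4_stream
#' @param stream A [sensor_stream()].
#' @export
write_e4_stream <- function(stream, path) {
  n_chan <- if (stream_kind(stream) == "ACC") 3L else 1L
  hdr <- c(
    paste(rep(format(stream_start(stream), digits = 15), n_chan), collapse = ","),
    paste(rep(format(stream_rate(stream), digits = 15), n_chan), collapse = ",")
  )
  body <- if (n_chan == 3L) {
    paste(format(stream$x, digits = 15, trim = TRUE, scientific = FALSE),
          format(stream$y, digits = 15, trim = TRUE, scientific = FALSE),
          format(stream$z, digits = 15, trim = TRUE, scientific = FALSE),
          sep = ",")
  } else {
    format(stream$value, digits = 15, trim = TRUE, scientific = FALSE)
  }
  writeLines(c(hdr, if (nrow(stream)) body), path)
  invisible(path)
}

#' Read / write inter-beat-interval event lists
#'
#' IBI files are event lists, not uniform streams: line 1 holds the absolute
#' stream start time (UTC epoch seconds), then one `offset_s,interval_s` row
#' per detected beat, where `offset_s` is seconds from the start time and
#' `interval_s` the inter-beat interval in seconds.
#'
#' @param path File path.
#' @return A tibble with columns `offset_s`, `interval_s` and attribute
#'   `start_time`.
#' @export
read_ibi <- function(path) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  lines <- readLines(path)
  if (length(lines) < 1) abort(sprintf("malformed header in %s: line 1 missing", path))
  start_time <- suppressWarnings(as.numeric(strsplit(lines[1], ",")[[1]][1]))
  if (is.na(start_time)) {
    abort(sprintf("malformed header in %s: line 1 is not numeric", path))
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body)) {
    parts <- strsplit(body, ",", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      abort(sprintf("parse error in %s: expected offset,interval rows", path))
    }
    m <- suppressWarnings(matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE))
    if (anyNA(m)) abort(sprintf("parse error in %s: non-numeric IBI row", path))
    out <- tibble::tibble(offset_s = m[, 1], interval_s = m[, 2])
  } else {
    out <- tibble::tibble(offset_s = numeric(0), interval_s = numeric(0))
  }
  validate_ibi(out)
  attr(out, "start_time") <- start_time
  out
}

#' @rdname read_ibi
#' @param ibi IBI tibble with `start_time` attribute (or pass `start_time`).
#' @param start_time Absolute start time; defaults to the tibble's attribute.
#' @export
write_ibi <- function(ibi, path, start_time = attr(ibi, "start_time")) {
  if (is.null(start_time)) abort("IBI start_time is required")
  writeLines(c(
    format(start_time, digits = 15),
    if (nrow(ibi)) {
      paste(format(ibi$offset_s, digits = 15, trim = TRUE, scientific = FALSE),
            format(ibi$interval_s, digits = 15, trim = TRUE, scientific = FALSE),
            sep = ",")
    }
  ), path)
  invisible(path)
}

validate_ibi <- function(ibi) {
  if (nrow(ibi)) {
    if (any(diff(ibi$offset_s) <= 0)) abort("IBI offsets must be strictly increasing")
    if (any(ibi$interval_s <= 0)) abort("IBI intervals must be positive")
  }
  invisible(ibi)
}

#' Read / write CGM traces
#'
#' `cgm.csv` has columns `timestamp` (UTC epoch seconds, nominal 300-s
#' spacing with gaps permitted) and `glucose_mg_dl`.
#'
#' @param path File path.
#' @return A tibble with columns `time`, `glucose_mg_dl`.
#' @export
read_cgm <- function(path) {
  df <- read_schema_csv(path, c("timestamp", "glucose_mg_dl"))
  out <- tibble::tibble(time = df$timestamp, glucose_mg_dl = df$glucose_mg_dl)
  validate_glucose(out)
  out
}

#' @rdname read_cgm
#' @param glucose Tibble with columns `time`, `glucose_mg_dl`.
#' @export
write_cgm <- function(glucose, path) {
  validate_glucose(glucose)
  readr::write_csv(
    tibble::tibble(timestamp = glucose$time, glucose_mg_dl = glucose$glucose_mg_dl),
    path
  )
  invisible(path)
}

validate_glucose <- function(glucose) {
  check_columns(glucose, c("time", "glucose_mg_dl"), "glucose series")
  if (any(!is.finite(glucose$glucose_mg_dl))) abort("glucose values must be finite")
  if (any(glucose$glucose_mg_dl < 0)) abort("glucose values must be >= 0")
  if (is.unsorted(glucose$time, strictly = TRUE)) {
    abort("glucose timestamps must be strictly increasing")
  }
  invisible(glucose)
}

#' Read / write food logs
#'
#' `food.csv` has columns `timestamp,calories_kcal,protein_g,carbs_g,sugar_g,label`;
#' one row per consumed meal, snack or caloric beverage.
#'
#' @param path File path.
#' @return A tibble with columns `time`, the four nutrient columns and `label`.
#' @export
read_food_log <- function(path) {
  df <- read_schema_csv(
    path, c("timestamp", "calories_kcal", "protein_g", "carbs_g", "sugar_g"),
    optional = "label"
  )
  out <- tibble::tibble(
    time = df$timestamp,
    calories_kcal = df$calories_kcal, protein_g = df$protein_g,
    carbs_g = df$carbs_g, sugar_g = df$sugar_g,
    label = if ("label" %in% names(df)) as.character(df$label) else NA_character_
  )
  validate_food(out)
  out
}

#' @rdname read_food_log
#' @param food Food-log tibble.
#' @export
write_food_log <- function(food, path) {
  validate_food(food)
  readr::write_csv(
    tibble::tibble(
      timestamp = food$time, calories_kcal = food$calories_kcal,
      protein_g = food$protein_g, carbs_g = food$carbs_g,
      sugar_g = food$sugar_g, label = food$label
    ),
    path
  )
  invisible(path)
}

validate_food <- function(food) {
  check_columns(food, c("time", "calories_kcal", "protein_g", "carbs_g", "sugar_g"),
                "food log")
  nutr <- c("calories_kcal", "protein_g", "carbs_g", "sugar_g")
  for (col in nutr) {
    if (any(food[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("food log column %s must be >= 0", col))
    }
  }
  if (is.unsorted(food$time)) abort("food log timestamps must be sorted")
  invisible(food)
}

#' Read / write demographics
#'
#' `demographics.csv` has columns `participant_id,sex,hba1c`; `sex` is
#' encoded numerically (0 = female, 1 = male) and `hba1c` is glycated
#' hemoglobin in percent (study range 5.2-6.4).
#'
#' @param path File path.
#' @return A tibble with those three columns.
#' @export
read_demographics <- function(path) {
  df <- read_schema_csv(path, c("participant_id", "sex", "hba1c"))
  tibble::tibble(
    participant_id = as.integer(df$participant_id),
    sex = as.numeric(df$sex), hba1c = as.numeric(df$hba1c)
  )
}

#' @rdname read_demographics
#' @param demographics Demographics tibble.
#' @export
write_demographics <- function(demographics, path) {
  check_columns(demographics, c("participant_id", "sex", "hba1c"), "demographics")
  readr::write_csv(demographics[, c("participant_id", "sex", "hba1c")], path)
  invisible(path)
}

# CSV with mandatory column set; empty cells become NA.
read_schema_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("schema error in %s: missing column%s %s", path,
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  df
}

#' Read / write feature tables
#'
#' The feature-table CSV has the fixed column order `participant_id`,
#' `epoch_start`, the 69 registered feature columns (see [feature_schema()]),
#' `glucose_target` and optionally `excursion_label`. Missing cells are
#' written as empty strings and read back as `NA`, so a table round-trips
#' losslessly.
#'
#' @param path File path.
#' @return A tibble in the registered column order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_double()))
  )
  expected <- feature_table_columns()
  unknown <- setdiff(names(df), c(expected, "excursion_label"))
  if (length(unknown)) {
    abort(sprintf("schema error in %s: unknown column%s %s", path,
                  if (length(unknown) > 1) "s" else "",
                  paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    abort(sprintf("schema error in %s: missing column%s %s", path,
                  if (length(missing) > 1) "s" else "",
                  paste(missing, collapse = ", ")))
  }
  if ("excursion_label" %in% names(df)) {
    lab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_select = "excursion_label",
                           col_types = readr::cols(.default = readr::col_character()))
    df$excursion_label <- factor(lab$excursion_label, levels = excursion_levels())
    df <- df[, c(expected, "excursion_label")]
  } else {
    df <- df[, expected]
  }
  df$participant_id <- as.integer(df$participant_id)
  df
}

#' @rdname read_feature_table
#' @param table Feature-table tibble.
#' @export
write_feature_table <- function(table, path) {
  expected <- feature_table_columns()
  cols <- if ("excursion_label" %in% names(table)) c(expected, "excursion_label") else expected
  check_columns(table, expected, "feature table")
  readr::write_csv(table[, cols], path, na = "")
  invisible(path)
}

feature_table_columns <- function() {
  c("participant_id", "epoch_start", feature_schema(), "glucose_target")
}

#' Participant records and cohort directories
#'
#' A participant record bundles one participant's identity (`participant_id`),
#' demographics (`sex`, `hba1c`), the four wearable streams, the IBI event
#' list, the CGM glucose trace and the food log. On disk each participant
#' occupies one directory `participant_<id>/` holding `HR.csv`, `EDA.csv`,
#' `TEMP.csv`, `ACC.csv`, `IBI.csv`, `cgm.csv`, `food.csv` and
#' `demographics.csv`.
#'
#' @param participant_id Integer id, unique within a cohort.
#' @param sex Numeric sex code (0 = female, 1 = male).
#' @param hba1c HbA1c percent.
#' @param streams Named list with elements `HR`, `EDA`, `TEMP`, `ACC`, each a
#'   [sensor_stream()].
#' @param ibi IBI tibble as returned by [read_ibi()].
#' @param glucose Glucose tibble as returned by [read_cgm()].
#' @param food Food-log tibble as returned by [read_food_log()].
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(participant_id, sex, hba1c, streams, ibi,
                               glucose, food) {
  missing_streams <- setdiff(c("HR", "EDA", "TEMP", "ACC"), names(streams))
  if (length(missing_streams)) {
    abort(sprintf("participant %s lacks stream(s): %s", participant_id,
                  paste(missing_streams, collapse = ", ")))
  }
  validate_glucose(glucose)
  validate_food(food)
  validate_ibi(ibi)
  structure(
    list(
      participant_id = as.integer(participant_id),
      sex = as.numeric(sex), hba1c = as.numeric(hba1c),
      streams = streams, ibi = ibi, glucose = glucose, food = food
    ),
    class = "participant_record"
  )
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf(
    "<participant_record %d> sex=%g hba1c=%.1f | %d glucose points, %d food entries\n",
    x$participant_id, x$sex, x$hba1c, nrow(x$glucose), nrow(x$food)
  ))
  invisible(x)
}

#' @rdname participant_record
#' @param p A `participant_record`.
#' @param dir Directory to write into / read from.
#' @export
write_participant <- function(p, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (kind in c("HR", "EDA", "TEMP", "ACC")) {
    write_e4_stream(p$streams[[kind]], file.path(dir, paste0(kind, ".csv")))
  }
  write_ibi(p$ibi, file.path(dir, "IBI.csv"))
  write_cgm(p$glucose, file.path(dir, "cgm.csv"))
  write_food_log(p$food, file.path(dir, "food.csv"))
  write_demographics(
    tibble::tibble(participant_id = p$participant_id, sex = p$sex, hba1c = p$hba1c),
    file.path(dir, "demographics.csv")
  )
  invisible(dir)
}

#' @rdname participant_record
#' @export
read_participant <- function(dir) {
  demo <- read_demographics(file.path(dir, "demographics.csv"))
  streams <- lapply(
    setNames(c("HR", "EDA", "TEMP", "ACC"), c("HR", "EDA", "TEMP", "ACC")),
    function(kind) read_e4_stream(file.path(dir, paste0(kind, ".csv")), kind)
  )
  participant_record(
    participant_id = demo$participant_id[1], sex = demo$sex[1], hba1c = demo$hba1c[1],
    streams = streams,
    ibi = read_ibi(file.path(dir, "IBI.csv")),
    glucose = read_cgm(file.path(dir, "cgm.csv")),
    food = read_food_log(file.path(dir, "food.csv"))
  )
}

#' @rdname participant_record
#' @param cohort List of `participant_record`s.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    write_participant(p, file.path(dir, sprintf("participant_%02d", p$participant_id)))
  }
  invisible(dir)
}

#' @rdname participant_record
#' @export
read_cohort <- function(dir) {
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  dirs <- dirs[grepl("participant_", basename(dirs))]
  if (!length(dirs)) abort(sprintf("no participant_* directories under %s", dir))
  lapply(dirs, read_participant)
}
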
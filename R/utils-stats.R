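#' Vector magnitude of a triaxial accelerometer sample
#'
#' Collapses the three accelerometer channels into a single magnitude,
#' `sqrt(x^2 + y^2 + z^2)`, in the device's native units of 1/64 g (so a
#' resting wrist reads close to 64).
#'
#' @param x,y,z Numeric vectors of equal length, one per axis.
#' @return Numeric vector of magnitudes.
#' @examples
#' vector_magnitude(3, 4, 0) # 5
#' @export
vector_magnitude <- function(x, y, z) {
  sqrt(x^2 + y^2 + z^2)
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' The n/((n-1)(n-2)) * sum(((x - mean)/s)^3) estimator. A window with zero
#' variance (flat sensor) is defined to have skewness 0 rather than NaN so
#' that flat-but-valid epochs do not propagate missingness.
#'
#' @param x Numeric vector.
#' @return Scalar skewness; `NA` when fewer than 3 values.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

# Excess kurtosis, bias-adjusted sample estimator; 0 for zero-variance input.
sample_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  g <- sum(((x - mean(x)) / s)^4)
  (n * (n + 1)) / ((n - 1) * (n - 2) * (n - 3)) * g -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

#' Seven summary statistics of a sensor window
#'
#' Mean, sample standard deviation, minimum, maximum, first and third
#' quartile (linear interpolation of order statistics, `quantile type = 7`),
#' and adjusted Fisher-Pearson skewness. Windows with fewer than 2 samples
#' return all seven as `NA` (a single reading cannot support a spread
#' estimate).
#'
#' @param x Numeric vector of samples falling in the window.
#' @param prefix Optional name prefix, e.g. `"hr"` gives `hr_mean`, ...
#' @return Named numeric vector of length 7.
#' @export
summary_stats <- function(x, prefix = NULL) {
  x <- x[!is.na(x)]
  stats <- if (length(x) < 2) {
    rep(NA_real_, 7)
  } else {
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    c(mean(x), sd(x), min(x), max(x), q[1], q[2], sample_skewness(x))
  }
  names(stats) <- paste0(
    if (is.null(prefix)) "" else paste0(prefix, "_"),
    c("mean", "sd", "min", "max", "q1", "q3", "skew")
  )
  stats
}

# Sum/mean/max over the w epochs strictly before each position.
# x is on a uniform epoch grid; window for position i is (i-w):(i-1).
# NAs are dropped within the window; an all-NA/empty window yields `empty`.
# Plain per-window summation keeps the arithmetic identical to a
# brute-force recomputation.
roll_prior <- function(x, width, fun = c("sum", "mean", "max"),
                       empty = NA_real_) {
  fun <- match.arg(fun)
  n <- length(x)
  out <- rep(empty, n)
  if (n == 0) return(out)
  f <- switch(fun, sum = sum, mean = mean, max = max)
  for (i in seq_len(n)) {
    lo <- max(1L, i - width)
    if (lo > i - 1L) next
    w <- x[lo:(i - 1L)]
    w <- w[!is.na(w)]
    if (length(w)) out[i] <- f(w)
  }
  out
}

# Epoch index (1-based) of absolute times on a grid anchored at `origin`.
epoch_index <- function(times, origin) {
  as.integer(floor((times - origin) / EPOCH_SECONDS)) + 1L
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing mandatory column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
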
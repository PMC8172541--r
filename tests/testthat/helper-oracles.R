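# Independent brute-force oracles. These re-derive every windowed quantity
# from first principles (explicit window membership scans), so they share no
# indexing logic with the package implementation.

# sum/mean/max over the `width` grid positions strictly before i
oracle_roll_prior <- function(x, width, fun, empty = NA_real_) {
  n <- length(x)
  out <- rep(empty, n)
  for (i in seq_len(n)) {
    idx <- which(seq_len(n) < i & seq_len(n) >= i - width)
    vals <- x[idx]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[i] <- fun(vals)
  }
  out
}

# nutrient sum over entries with time in [t - w, t)
oracle_food_sum <- function(food_times, food_values, t, w_seconds) {
  sum(food_values[food_times >= t - w_seconds & food_times < t])
}

# rolling 24-h mean/sd of glucose, excluding the current point
oracle_roll_baseline <- function(times, values, i, window_s = 86400) {
  win <- values[times >= times[i] - window_s & times < times[i]]
  list(n = length(win),
       mean = if (length(win)) mean(win) else NA_real_,
       sd = if (length(win) >= 2) sd(win) else NA_real_)
}

# O(n^2) peak oracle: every local max; prominence by full left/right sweeps;
# then drop peaks too close to a taller (or equally tall, earlier) kept one.
oracle_peak_count <- function(x, min_distance = 4, min_prominence = 0.3) {
  n <- length(x)
  if (n < 3) return(0L)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && x[j + 1] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(0L)
  # min-distance: iterate candidates from tallest (earlier wins ties)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || min(abs(kept - p)) >= min_distance) kept <- c(kept, p)
  }
  kept <- sort(kept)
  proms <- vapply(kept, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[(max(higher_l) + 1):(p - 1)]) else min(left)
    right <- x[(p + 1):n]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[1:(min(higher_r) - 1)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  sum(proms >= min_prominence)
}

# HRV from first principles
oracle_hrv <- function(intervals_s) {
  ms <- intervals_s * 1000
  n <- length(ms)
  out <- list(ibi_mean = NA_real_, ibi_median = NA_real_, ibi_max = NA_real_,
              ibi_min = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
              nn50 = NA_real_, pnn50 = NA_real_)
  if (n == 0) return(out)
  out$ibi_mean <- sum(ms) / n
  out$ibi_median <- median(ms)
  out$ibi_max <- max(ms)
  out$ibi_min <- min(ms)
  if (n >= 2) {
    m <- out$ibi_mean
    out$sdnn <- sqrt(sum((ms - m)^2) / (n - 1))
    d <- ms[-1] - ms[-n]
    out$rmssd <- sqrt(sum(d^2) / length(d))
    out$nn50 <- sum(abs(d) > 50)
    out$pnn50 <- out$nn50 / n
  }
  out
}

# adjusted Fisher-Pearson skewness / excess kurtosis from raw moments
oracle_skew <- function(x) {
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / (n - 1))
  if (s == 0) return(0)
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}
oracle_kurtosis <- function(x) {
  n <- length(x)
  s <- sqrt(sum((x - mean(x))^2) / (n - 1))
  if (s == 0) return(0)
  (n * (n + 1)) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# a gaussian bump train for peak tests
make_bump_signal <- function(n, centers, heights, width = 6, baseline = 0.3,
                             rate = 4) {
  t <- seq_len(n)
  x <- rep(baseline, n)
  for (k in seq_along(centers)) {
    x <- x + heights[k] * exp(-((t - centers[k])^2) / (2 * width^2))
  }
  x
}
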
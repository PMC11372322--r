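# Independent brute-force oracles used across the suite.  These implement
# the definitions directly (explicit loops, O(n^2) where that is simplest)
# and deliberately share no code with the package internals.

oracle_local_maxima <- function(x) {
  n <- length(x)
  idx <- integer(0)
  for (i in 2:(n - 1))
    if (x[i - 1] < x[i] && x[i] >= x[i + 1]) idx <- c(idx, i)
  idx
}

oracle_prominence <- function(x, i) {
  n <- length(x)
  higher_l <- which(x[seq_len(i - 1)] > x[i])
  lb <- if (length(higher_l)) min(x[(max(higher_l) + 1):i]) else min(x[1:i])
  higher_r <- which(x[(i + 1):n] > x[i]) + i
  rb <- if (length(higher_r)) min(x[i:(min(higher_r) - 1)]) else min(x[i:n])
  x[i] - max(lb, rb)
}

oracle_global_filter <- function(prom, frac) {
  which(prom > frac * mean(prom))
}

oracle_window_filter <- function(prom, frac, width) {
  m <- length(prom)
  w <- min(width, m)
  half <- (width - 1) %/% 2
  keep <- logical(m)
  for (i in seq_len(m)) {
    s <- i - half
    if (s < 1) s <- 1
    if (s > m - w + 1) s <- m - w + 1
    keep[i] <- !(prom[i] < frac * mean(prom[s:(s + w - 1)]))
  }
  which(keep)
}

oracle_quartile_reject <- function(x, window, mult, qtype = 7) {
  rejected <- logical(length(x))
  starts <- seq(1, length(x), by = window)
  for (s in starts) {
    b <- s:min(s + window - 1, length(x))
    q <- as.numeric(stats::quantile(x[b], c(0.25, 0.75), type = qtype))
    lo <- q[1] - mult * (q[2] - q[1])
    hi <- q[2] + mult * (q[2] - q[1])
    rejected[b] <- x[b] < lo | x[b] > hi
  }
  which(rejected)
}

oracle_successive_reject <- function(x, frac) {
  rejected <- logical(length(x))
  ref <- x[1]
  for (i in seq_along(x)[-1]) {
    if (abs(x[i] - ref) / ref > frac) rejected[i] <- TRUE
    else ref <- x[i]
  }
  which(rejected)
}

oracle_rate_reject <- function(x, min_bpm, max_bpm) {
  which(60000 / x < min_bpm | 60000 / x > max_bpm)
}

# ICC(A,1) from stats::aov mean squares (independent ANOVA route)
oracle_icc_a1 <- function(x, y) {
  n <- length(x)
  d <- data.frame(val = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  meth = factor(rep(1:2, each = n)))
  # aov warns on zero-residual tables; the mean squares are still exact
  ms <- suppressWarnings(
    anova(stats::aov(val ~ subj + meth, data = d))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# One-to-one closest-wins event matching, written as an explicit
# candidate-elimination loop.
oracle_match_events <- function(a, b, tol) {
  m <- rep(NA_integer_, length(a))
  taken_a <- logical(length(a))
  taken_b <- logical(length(b))
  repeat {
    best <- c(NA, NA); best_d <- Inf
    for (i in which(!taken_a)) for (j in which(!taken_b)) {
      d <- abs(a[i] - b[j])
      if (d <= tol && d < best_d) { best <- c(i, j); best_d <- d }
    }
    if (!is.finite(best_d)) break
    m[best[1]] <- best[2]
    taken_a[best[1]] <- TRUE
    taken_b[best[2]] <- TRUE
  }
  m
}

make_series <- function(intervals_ms, start = 0) {
  beats <- start + cumsum(intervals_ms) / 1000
  interval_series(beats, intervals_ms)
}
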
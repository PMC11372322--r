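#' Time-domain HRV summary of an interval series
#'
#' @param series An [interval_series()] with >= 2 valid intervals, or a bare
#'   numeric vector of intervals in ms.
#' @return A list of class `hrv_summary`: `n_beats`, `mean_pi` (ms) and
#'   `sdnn` (sample standard deviation of the valid intervals, ms; the
#'   classical normal-to-normal SD after artifact removal).
#' @export
hrv_summary <- function(series) {
  x <- if (inherits(series, "interval_series")) valid_intervals(series)
       else as.numeric(series)
  if (length(x) < 2L)
    stop("HRV summary needs at least 2 valid intervals", call. = FALSE)
  structure(list(n_beats = length(x), mean_pi = mean(x), sdnn = stats::sd(x)),
            class = "hrv_summary")
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf("<hrv_summary> n = %d, mean PI = %.1f ms, SDNN = %.1f ms\n",
              x$n_beats, x$mean_pi, x$sdnn))
  invisible(x)
}

#' Pearson product-moment correlation with two-tailed p value
#'
#' @param x,y Paired numeric vectors (n >= 3, each with nonzero variance).
#' @return A list `r`, `p` (two-tailed, from the t transform on n - 2 df)
#'   and `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a zero-variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-way random-effects absolute-agreement ICC for two methods
#'
#' Single-rater intraclass correlation ICC(A,1) from the two-way ANOVA
#' decomposition of an n-subjects-by-2-methods table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{k = 2}, where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the
#' rows (subjects), columns (methods) and error mean squares.  Absolute
#' agreement penalises systematic offsets between methods, unlike a
#' consistency ICC.  The confidence interval is the standard F-based interval
#' for this form (Satterthwaite degrees of freedom for the lower/upper
#' bounds).
#'
#' @param x,y Measurements of the same n >= 3 subjects by the two methods.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n`, `k`, `degenerate` (`TRUE`, with
#'   `icc = 0` and a warning, when there is no between-subject variance to
#'   agree on).
#' @export
icc_absolute_agreement <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("ICC needs >= 3 subjects measured by both methods", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("ICC inputs must be finite (no missing cells)", call. = FALSE)
  n <- length(x); k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    warning("no between-subject variance; ICC reported as 0")
    return(structure(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                          ms_rows = msr, ms_cols = msc, ms_error = mse,
                          n = n, k = k, degenerate = TRUE),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  if (mse == 0 && msc <= msr) {
    # perfect agreement: the interval degenerates at the top
    ci <- c(1, 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 ms_rows = msr, ms_cols = msc, ms_error = mse,
                 n = n, k = k, degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(A,1) = %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
              x$icc, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bland-Altman method-comparison analysis
#'
#' Computes per-pair differences `d = x - y` and means `m = (x + y)/2`, the
#' mean difference (bias), the sample SD of the differences, the 95% limits
#' of agreement `mean(d) +/- loa_multiplier * sd(d)`, a paired two-tailed
#' t test of the fixed bias against zero, and the proportional-bias
#' regression of `d` on `m` (OLS slope, its SE, two-tailed p and R-squared).
#'
#' @param x,y Paired measurements by methods A and B (difference direction is
#'   `x - y`; n >= 3).
#' @param loa_multiplier SD multiplier for the limits of agreement
#'   (default 1.96, the two-sided 95% normal quantile).
#' @return A list of class `bland_altman`: `n`, `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `fixed_bias_t`, `fixed_bias_p`,
#'   `prop_slope_b`, `prop_slope_se`, `prop_p`, `prop_r2`.
#' @export
bland_altman <- function(x, y, loa_multiplier = 1.96) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("Bland-Altman needs >= 3 pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd > 0) {
    tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
    tstat <- unname(tt$statistic); tp <- tt$p.value
  } else {
    tstat <- if (md == 0) 0 else Inf
    tp <- if (md == 0) 1 else 0
  }
  if (stats::var(m) > 0 && sdd > 0) {
    fit <- summary(stats::lm(d ~ m))
    co <- stats::coef(fit)
    slope <- co["m", "Estimate"]; se <- co["m", "Std. Error"]
    pp <- co["m", "Pr(>|t|)"]; r2 <- fit$r.squared
  } else {
    slope <- 0; se <- NA_real_; pp <- NA_real_; r2 <- 0
  }
  structure(list(n = length(x), mean_diff = md, sd_diff = sdd,
                 loa_lower = md - loa_multiplier * sdd,
                 loa_upper = md + loa_multiplier * sdd,
                 fixed_bias_t = tstat, fixed_bias_p = tp,
                 prop_slope_b = slope, prop_slope_se = se, prop_p = pp,
                 prop_r2 = r2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<bland_altman> bias %.2f (SD %.2f) ms, LoA [%.1f, %.1f], ",
                     "fixed-bias p = %.3g, slope b = %.4f (p = %.3g, R2 = %.2f)\n"),
              x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper,
              x$fixed_bias_p, x$prop_slope_b, x$prop_p, x$prop_r2))
  invisible(x)
}

#' Limits of agreement from a printed bias and SD
#'
#' Convenience for re-deriving the interval quoted with a Bland-Altman plot
#' from its reported mean difference and SD of differences.
#'
#' @param mean_diff Mean between-method difference.
#' @param sd_diff SD of the differences.
#' @param loa_multiplier SD multiplier (default 1.96).
#' @return Numeric vector `c(lower, upper)`.
#' @export
limits_of_agreement <- function(mean_diff, sd_diff, loa_multiplier = 1.96) {
  c(lower = mean_diff - loa_multiplier * sd_diff,
    upper = mean_diff + loa_multiplier * sd_diff)
}

#' Full method-comparison battery on paired beats or subject summaries
#'
#' At `level = "beat_by_beat"` the battery (Pearson, absolute-agreement ICC,
#' Bland-Altman with ECG-minus-PPG differences, per-method HRV summaries)
#' runs on one recording's paired intervals.  At `level = "subject_means"`
#' `pairing` must be a *list* of pairings (one per subject) and the battery
#' runs across subjects on the chosen per-subject summary (`metric`:
#' mean pulse interval or SDNN).
#'
#' @param pairing A [pair_beats()] result, or a list of them for
#'   `"subject_means"`.
#' @param level `"beat_by_beat"` or `"subject_means"`.
#' @param metric Subject-level summary compared at `"subject_means"`.
#' @return A list of class `agreement_report`: `level`, `metric`, `n`,
#'   `pearson`, `icc`, `bland_altman` (ECG minus PPG), and `hrv` (per-method
#'   summaries of the values compared).
#' @export
compare_methods <- function(pairing,
                            level = c("beat_by_beat", "subject_means"),
                            metric = c("mean_pi", "sdnn")) {
  level <- match.arg(level)
  metric <- match.arg(metric)
  if (level == "beat_by_beat") {
    stopifnot(inherits(pairing, "beat_pairing"))
    ecg <- pairing$pairs$ecg_interval_ms
    ppg <- pairing$pairs$ppg_interval_ms
    metric <- "interval_ms"
  } else {
    stopifnot(is.list(pairing), length(pairing) >= 3L)
    summ <- function(p, col) {
      stopifnot(inherits(p, "beat_pairing"))
      h <- hrv_summary(p$pairs[[col]])
      if (metric == "mean_pi") h$mean_pi else h$sdnn
    }
    ecg <- vapply(pairing, summ, numeric(1), col = "ecg_interval_ms")
    ppg <- vapply(pairing, summ, numeric(1), col = "ppg_interval_ms")
  }
  ident <- isTRUE(all.equal(ecg, ppg, tolerance = 0))
  pe <- if (ident) list(r = 1, p = 0, n = length(ecg)) else pearson_cor(ecg, ppg)
  structure(list(level = level, metric = metric, n = length(ecg),
                 pearson = pe,
                 icc = icc_absolute_agreement(ecg, ppg),
                 bland_altman = bland_altman(ecg, ppg),
                 hrv = list(ecg = hrv_summary(ecg), ppg = hrv_summary(ppg))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s (%s), n = %d\n", x$level, x$metric, x$n))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson$r, x$pearson$p))
  cat(sprintf("  ICC(A,1) = %.3f [%.3f, %.3f]\n",
              x$icc$icc, x$icc$ci_low, x$icc$ci_high))
  print(x$bland_altman)
  invisible(x)
}
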
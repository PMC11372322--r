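#' Per-beat pulse-interval series with rejection codes
#'
#' @param beat_times Time (s) of the peak that *ends* each interval; strictly
#'   increasing.
#' @param intervals Interval durations in milliseconds (> 0).
#' @param status Per-interval code: `"valid"`, `"rejected_quartile"`,
#'   `"rejected_successive"` or `"rejected_rate_bounds"`.
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(beat_times, intervals,
                            status = rep("valid", length(intervals))) {
  beat_times <- as.numeric(beat_times)
  intervals <- as.numeric(intervals)
  status <- as.character(status)
  n <- length(intervals)
  if (length(beat_times) != n || length(status) != n)
    stop("interval series fields must have equal length", call. = FALSE)
  if (any(intervals <= 0))
    stop("intervals must be positive", call. = FALSE)
  if (n > 1L && any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  codes <- c("valid", "rejected_quartile", "rejected_successive",
             "rejected_rate_bounds")
  if (!all(status %in% codes))
    stop("unknown interval status code", call. = FALSE)
  structure(list(beat_times = beat_times, intervals = intervals,
                 status = status),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %d intervals (%d valid), mean %.1f ms\n",
              length(x$intervals), sum(x$status == "valid"),
              mean(x$intervals[x$status == "valid"])))
  invisible(x)
}

#' Valid intervals of a series
#' @param series An [interval_series()].
#' @return Numeric vector of the intervals still marked `"valid"`, in ms.
#' @export
valid_intervals <- function(series) {
  series$intervals[series$status == "valid"]
}

#' Configuration of the multistep interval artifact rejection
#'
#' @param window_intervals Segment length, in intervals, over which the
#'   quartile thresholds are computed (default 200, the device's on-line
#'   quality-analysis window length).
#' @param fence_multiplier IQR multiplier for the quartile fences.  The
#'   default 1.5 gives Tukey fences `Q1 - 1.5 IQR` / `Q3 + 1.5 IQR`; 0
#'   recovers the literal reading in which everything outside `[Q1, Q3]` is
#'   removed (which would discard about half of all beats).
#' @param successive_diff_fraction Maximum tolerated relative difference
#'   between an interval and the most recent accepted interval (default 0.20).
#' @param min_bpm,max_bpm Exclusive physiological heart-rate bounds
#'   (defaults 20 and 200 bpm; intervals of exactly 3000 or 300 ms are kept).
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(window_intervals = 200L, fence_multiplier = 1.5,
                            successive_diff_fraction = 0.20,
                            min_bpm = 20, max_bpm = 200, quantile_type = 7L) {
  if (window_intervals < 4L)
    stop("`window_intervals` must be >= 4", call. = FALSE)
  if (fence_multiplier < 0)
    stop("`fence_multiplier` must be >= 0", call. = FALSE)
  if (successive_diff_fraction <= 0 || successive_diff_fraction >= 1)
    stop("`successive_diff_fraction` must lie in (0, 1)", call. = FALSE)
  if (!(min_bpm > 0 && min_bpm < max_bpm))
    stop("need 0 < min_bpm < max_bpm", call. = FALSE)
  structure(list(window_intervals = as.integer(window_intervals),
                 fence_multiplier = fence_multiplier,
                 successive_diff_fraction = successive_diff_fraction,
                 min_bpm = min_bpm, max_bpm = max_bpm,
                 quantile_type = as.integer(quantile_type)),
            class = "cleaning_config")
}

#' Pulse intervals between successive valid peaks
#'
#' @param peaks A [peak_set()] with at least 2 peaks.
#' @return An [interval_series()]: `intervals[i]` is the time from peak `i`
#'   to peak `i+1` in ms, stamped with the time of the ending peak; all
#'   statuses `"valid"`.
#' @export
compute_intervals <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks) < 2L)
    stop("need at least 2 peaks to form intervals", call. = FALSE)
  t <- peaks$peak_times
  interval_series(beat_times = t[-1], intervals = diff(t) * 1000)
}

#' Windowed quartile fence filter
#'
#' Partitions the currently valid intervals, in time order, into consecutive
#' segments of `window_intervals` (the last segment may be shorter).  Within
#' each segment the first and third quartiles set the thresholds: intervals
#' outside `[Q1 - f*IQR, Q3 + f*IQR]` (with `f = fence_multiplier`) are marked
#' `rejected_quartile`.
#'
#' @param series An [interval_series()].
#' @param cfg A [cleaning_config()].
#' @return The series with updated statuses; interval values untouched.
#' @export
quartile_window_filter <- function(series, cfg = cleaning_config()) {
  stopifnot(inherits(series, "interval_series"))
  idx <- which(series$status == "valid")
  if (length(idx) == 0L) return(series)
  blocks <- split(idx, (seq_along(idx) - 1L) %/% cfg$window_intervals)
  for (b in blocks) {
    x <- series$intervals[b]
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE,
                         type = cfg$quantile_type)
    iqr <- q[2] - q[1]
    lo <- q[1] - cfg$fence_multiplier * iqr
    hi <- q[2] + cfg$fence_multiplier * iqr
    series$status[b[x < lo | x > hi]] <- "rejected_quartile"
  }
  series
}

#' Successive-difference implausibility filter
#'
#' Scans the valid intervals in time order, marking `rejected_successive`
#' any interval whose relative difference from the most recent *accepted*
#' interval exceeds `successive_diff_fraction` (default 20%); physiological
#' beat-to-beat changes of that size are implausible at rest.  The first
#' valid interval seeds the reference and rejected intervals never become the
#' reference, so one artifact cannot poison the comparisons that follow.
#'
#' @inheritParams quartile_window_filter
#' @return The series with updated statuses.
#' @export
successive_difference_filter <- function(series, cfg = cleaning_config()) {
  stopifnot(inherits(series, "interval_series"))
  idx <- which(series$status == "valid")
  if (length(idx) < 2L) return(series)
  ref <- series$intervals[idx[1]]
  for (i in idx[-1]) {
    x <- series$intervals[i]
    if (abs(x - ref) / ref > cfg$successive_diff_fraction)
      series$status[i] <- "rejected_successive"
    else
      ref <- x
  }
  series
}

#' Physiological heart-rate bounds filter
#'
#' Marks `rejected_rate_bounds` any valid interval implying a heart rate
#' strictly below `min_bpm` or strictly above `max_bpm` (defaults: 20 and
#' 200 bpm, i.e. intervals above 3000 ms or below 300 ms; the bounds are
#' exclusive, so 300 ms and 3000 ms survive).
#'
#' @inheritParams quartile_window_filter
#' @return The series with updated statuses.
#' @export
rate_bounds_filter <- function(series, cfg = cleaning_config()) {
  stopifnot(inherits(series, "interval_series"))
  idx <- which(series$status == "valid")
  bpm <- 60000 / series$intervals[idx]
  series$status[idx[bpm < cfg$min_bpm | bpm > cfg$max_bpm]] <-
    "rejected_rate_bounds"
  series
}

#' Multistep pulse-interval artifact rejection
#'
#' Applies, in order, [quartile_window_filter()],
#' [successive_difference_filter()] and [rate_bounds_filter()].  Statuses
#' accumulate (a rejected interval is never reconsidered) and interval values
#' are never modified.
#'
#' @inheritParams quartile_window_filter
#' @param verbose Log per-stage rejection counts to `stderr`.
#' @return The cleaned series, with attribute `stage_counts` (named integer
#'   vector of rejections per stage).
#' @export
clean_intervals <- function(series, cfg = cleaning_config(), verbose = FALSE) {
  stopifnot(inherits(series, "interval_series"))
  s1 <- quartile_window_filter(series, cfg)
  s2 <- successive_difference_filter(s1, cfg)
  s3 <- rate_bounds_filter(s2, cfg)
  counts <- c(quartile = sum(s1$status == "rejected_quartile"),
              successive = sum(s2$status == "rejected_successive"),
              rate_bounds = sum(s3$status == "rejected_rate_bounds"))
  if (verbose)
    message(sprintf("interval cleaning: quartile %d, successive %d, rate %d",
                    counts[1], counts[2], counts[3]))
  attr(s3, "stage_counts") <- counts
  s3
}

#' Rejection counts by stage
#'
#' @param series An [interval_series()] (typically after [clean_intervals()]).
#' @return Named list of interval counts: total, valid and per rejection code.
#' @export
rejection_summary <- function(series) {
  stopifnot(inherits(series, "interval_series"))
  list(total = length(series$intervals),
       valid = sum(series$status == "valid"),
       rejected_quartile = sum(series$status == "rejected_quartile"),
       rejected_successive = sum(series$status == "rejected_successive"),
       rejected_rate_bounds = sum(series$status == "rejected_rate_bounds"))
}
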
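#' Configuration of the PPG peak-extraction pipeline
#'
#' Bundles the tunable constants of the camera-PPG processing chain: a
#' 0.75--3 Hz Butterworth bandpass (pulse fundamentals for 45--180 bpm),
#' a 5-frame unit-sum smoothing window, 180 Hz cubic-spline resampling,
#' and the two prominence validity criteria (a peak must exceed 30% of the
#' mean prominence of all detected maxima, and 75% of the mean prominence
#' within a sliding 5-peak window, the latter aimed at dicrotic maxima).
#'
#' @param band_low,band_high Bandpass corner frequencies in Hz.
#' @param filter_order Butterworth order of the one-way filter; it is applied
#'   forward and backward (zero phase), doubling the effective order.
#' @param smooth_window_len Smoothing window length in frames (odd, >= 3).
#' @param smooth_window_shape `"hann"` (default) or `"flat"` moving average.
#' @param resample_rate Output rate of the spline resampling stage, Hz.
#' @param global_prominence_fraction Fraction of the mean prominence of all
#'   maxima a peak must exceed to stay valid.
#' @param window_prominence_fraction Fraction of the windowed mean prominence
#'   below which a peak is discarded.
#' @param prominence_window_peaks Number of peaks in the sliding window.
#' @param invert_luminosity Negate the luminosity before filtering.  Blood
#'   volume absorbs light, so the systolic pulse is a luminosity *dip*;
#'   inversion makes pulses local maxima, which the detector expects.
#' @return A list of class `ppg_config`.
#' @export
ppg_config <- function(band_low = 0.75, band_high = 3.0, filter_order = 2L,
                       smooth_window_len = 5L,
                       smooth_window_shape = c("hann", "flat"),
                       resample_rate = 180,
                       global_prominence_fraction = 0.30,
                       window_prominence_fraction = 0.75,
                       prominence_window_peaks = 5L,
                       invert_luminosity = TRUE) {
  smooth_window_shape <- match.arg(smooth_window_shape)
  if (!(band_low > 0 && band_low < band_high && band_high < resample_rate / 2))
    stop("need 0 < band_low < band_high < resample_rate/2", call. = FALSE)
  if (global_prominence_fraction <= 0 || global_prominence_fraction >= 1 ||
      window_prominence_fraction <= 0 || window_prominence_fraction >= 1)
    stop("prominence fractions must lie in (0, 1)", call. = FALSE)
  if (smooth_window_len < 3L || smooth_window_len %% 2L == 0L)
    stop("`smooth_window_len` must be odd and >= 3", call. = FALSE)
  if (prominence_window_peaks < 1L)
    stop("`prominence_window_peaks` must be >= 1", call. = FALSE)
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order),
                 smooth_window_len = as.integer(smooth_window_len),
                 smooth_window_shape = smooth_window_shape,
                 resample_rate = resample_rate,
                 global_prominence_fraction = global_prominence_fraction,
                 window_prominence_fraction = window_prominence_fraction,
                 prominence_window_peaks = as.integer(prominence_window_peaks),
                 invert_luminosity = isTRUE(invert_luminosity)),
            class = "ppg_config")
}

# Zero-phase filtering with odd-reflection end padding.  The pad absorbs the
# start-up transient of the 0.75 Hz corner (~3 periods) so record ends are
# usable; signal::filtfilt alone leaves a visible edge swing.
filtfilt_padded <- function(filt, x, pad_len) {
  n <- length(x)
  pad_len <- min(pad_len, n - 1L)
  left <- 2 * x[1] - x[(pad_len + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad_len)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad_len + 1L):(pad_len + n)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies the configured Butterworth bandpass forward and backward
#' (zero phase, so peak times are not displaced), with odd-reflection end
#' padding sized to about three periods of the low corner frequency.
#'
#' @param signal A [uniform_signal()]; its rate must exceed `2 * band_high`.
#' @param cfg A [ppg_config()].
#' @return A [uniform_signal()] with the same length, rate and start time.
#' @export
bandpass_filter <- function(signal, cfg = ppg_config()) {
  stopifnot(inherits(signal, "uniform_signal"))
  n <- length(signal$values)
  if (signal$rate <= 2 * cfg$band_high)
    stop("sampling rate must exceed twice the upper band edge", call. = FALSE)
  if (n <= 3 * (2L * cfg$filter_order + 1L))
    stop("signal too short for zero-phase filtering", call. = FALSE)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / (signal$rate / 2),
                       type = "pass")
  pad <- as.integer(ceiling(3 * signal$rate / cfg$band_low))
  # the mean is outside the passband anyway; removing it first keeps the
  # start-up transient of the low corner from leaking numerical DC residue
  x <- signal$values - mean(signal$values)
  uniform_signal(filtfilt_padded(bf, x, pad),
                 rate = signal$rate, start_time = signal$start_time)
}

smoothing_window <- function(len, shape) {
  w <- switch(shape,
              hann = 0.5 - 0.5 * cos(2 * pi * (0:(len - 1)) / (len - 1)),
              flat = rep(1, len))
  w / sum(w)
}

#' Smooth a signal by convolution with a unit-sum window
#'
#' Convolves the signal with a symmetric window scaled to unit sum (Hann by
#' default, flat for a plain moving average).  Record ends are handled by
#' reflection padding so output length equals input length; a unit-sum
#' symmetric window leaves constants (and interior affine trends) unchanged.
#'
#' @inheritParams bandpass_filter
#' @return A [uniform_signal()] with the same length, rate and start time.
#' @export
smooth_signal <- function(signal, cfg = ppg_config()) {
  stopifnot(inherits(signal, "uniform_signal"))
  len <- cfg$smooth_window_len
  x <- signal$values
  n <- length(x)
  if (len > n)
    stop("smoothing window longer than the signal", call. = FALSE)
  w <- smoothing_window(len, cfg$smooth_window_shape)
  h <- (len - 1L) %/% 2L
  xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
  y <- stats::filter(xp, w, method = "convolution", sides = 2)
  uniform_signal(as.numeric(y[(h + 1L):(h + n)]),
                 rate = signal$rate, start_time = signal$start_time)
}

# Not-a-knot cubic spline through (x, y), evaluated at xout.  Solves the
# moment (second-derivative) system; the not-a-knot rows demand a continuous
# third derivative at the second and penultimate knots, which makes the
# interpolant reproduce cubic polynomials exactly.
spline_not_a_knot <- function(x, y, xout) {
  n <- length(x)
  if (n < 4L) stop("not-a-knot spline needs at least 4 points", call. = FALSE)
  h <- diff(x)
  i <- 2:(n - 1)
  rows <- c(1L, 1L, 1L, rep(i, each = 3L), n, n, n)
  cols <- c(1L, 2L, 3L,
            as.vector(rbind(i - 1L, i, i + 1L)),
            n - 2L, n - 1L, n)
  vals <- c(h[2], -(h[1] + h[2]), h[1],
            as.vector(rbind(h[i - 1], 2 * (h[i - 1] + h[i]), h[i])),
            h[n - 1], -(h[n - 2] + h[n - 1]), h[n - 2])
  rhs <- c(0, 6 * diff(diff(y) / h), 0)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  M <- as.numeric(Matrix::solve(A, rhs))
  k <- pmin(pmax(findInterval(xout, x), 1L), n - 1L)
  hk <- h[k]
  dl <- x[k + 1L] - xout
  dr <- xout - x[k]
  M[k] * dl^3 / (6 * hk) + M[k + 1L] * dr^3 / (6 * hk) +
    (y[k] / hk - M[k] * hk / 6) * dl +
    (y[k + 1L] / hk - M[k + 1L] * hk / 6) * dr
}

#' Resample a signal with a not-a-knot cubic spline
#'
#' Fits a cubic spline (not-a-knot end conditions) through the input samples
#' and evaluates it on a uniform grid at `cfg$resample_rate` covering the full
#' input duration: `floor(duration * rate) + 1` samples starting at the input
#' start time.
#'
#' @inheritParams bandpass_filter
#' @return A [uniform_signal()] at `cfg$resample_rate`.
#' @export
resample_cubic_spline <- function(signal, cfg = ppg_config()) {
  stopifnot(inherits(signal, "uniform_signal"))
  n <- length(signal$values)
  if (n < 4L)
    stop("need at least 4 samples to fit a cubic spline", call. = FALSE)
  tin <- signal_times(signal)
  duration <- tin[n] - tin[1]
  m <- floor(duration * cfg$resample_rate)
  tout <- tin[1] + (0:m) / cfg$resample_rate
  uniform_signal(spline_not_a_knot(tin, signal$values, tout),
                 rate = cfg$resample_rate, start_time = tin[1])
}

# Topographic prominence of peak index i: height above the higher of the two
# lowest descents before meeting a strictly higher sample (or the record edge).
peak_prominences <- function(values, peak_idx) {
  n <- length(values)
  vapply(peak_idx, function(i) {
    v <- values[i]
    j <- i; lmin <- v
    while (j > 1L && values[j - 1L] <= v) {
      j <- j - 1L
      if (values[j] < lmin) lmin <- values[j]
    }
    j <- i; rmin <- v
    while (j < n && values[j + 1L] <= v) {
      j <- j + 1L
      if (values[j] < rmin) rmin <- values[j]
    }
    v - max(lmin, rmin)
  }, numeric(1))
}

#' Detect local maxima by simple neighbour comparison
#'
#' A sample is a peak when it strictly exceeds its left neighbour and is at
#' least its right neighbour (so a flat plateau contributes its first sample).
#' Prominence is computed for every peak by the standard topographic
#' definition.
#'
#' @param signal A [uniform_signal()] of length >= 3.
#' @return A [peak_set()]; possibly empty.
#' @export
detect_local_maxima <- function(signal) {
  stopifnot(inherits(signal, "uniform_signal"))
  x <- signal$values
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  peak_set(peak_times = signal$start_time + (idx - 1L) / signal$rate,
           peak_indices = idx,
           prominences = peak_prominences(x, idx))
}

subset_peaks <- function(peaks, keep) {
  peak_set(peaks$peak_times[keep], peaks$peak_indices[keep],
           peaks$prominences[keep])
}

#' Global prominence validity filter
#'
#' Retains peaks whose prominence exceeds
#' `global_prominence_fraction` (default 30%) of the mean prominence of all
#' detected maxima.
#'
#' @param peaks A [peak_set()].
#' @param cfg A [ppg_config()].
#' @return The filtered [peak_set()], order preserved.
#' @export
prominence_filter_global <- function(peaks, cfg = ppg_config()) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks) == 0L) return(peaks)
  thr <- cfg$global_prominence_fraction * mean(peaks$prominences)
  subset_peaks(peaks, peaks$prominences > thr)
}

#' Sliding-window prominence filter
#'
#' For each peak, a window of `prominence_window_peaks` peaks (default 5) is
#' placed around it, clamped at the list ends so the window keeps its full
#' width whenever enough peaks exist; the peak is discarded when its
#' prominence falls below `window_prominence_fraction` (default 75%) of the
#' mean prominence inside its window.  All windows are evaluated against the
#' original, pre-filter peak list in a single pass.  This is the stage that
#' removes dicrotic (diastolic) maxima misdetected between systolic peaks.
#'
#' @inheritParams prominence_filter_global
#' @return The filtered [peak_set()], order preserved.
#' @export
prominence_filter_window <- function(peaks, cfg = ppg_config()) {
  stopifnot(inherits(peaks, "peak_set"))
  m <- length(peaks)
  if (m == 0L) return(peaks)
  w <- min(cfg$prominence_window_peaks, m)
  half <- (cfg$prominence_window_peaks - 1L) %/% 2L
  pr <- peaks$prominences
  keep <- vapply(seq_len(m), function(i) {
    s <- min(max(1L, i - half), m - w + 1L)
    pr[i] >= cfg$window_prominence_fraction * mean(pr[s:(s + w - 1L)])
  }, logical(1))
  subset_peaks(peaks, keep)
}

#' Extract valid systolic peak times from a raw camera-PPG recording
#'
#' Runs the full chain on a frame-luminosity series: regularisation to the
#' nominal frame grid (optionally negating luminosity so pulses point up),
#' zero-phase Butterworth bandpass, unit-sum window smoothing, 180 Hz cubic
#' spline resampling, neighbour-comparison peak detection, then the global and
#' sliding-window prominence validity filters.
#'
#' @param raw A [frame_series()] of at least 10 s duration.
#' @param cfg A [ppg_config()].
#' @param verbose Log per-stage peak counts to `stderr`.
#' @return A [peak_set()] of valid systolic peaks on the resampled grid, with
#'   attribute `stage_counts` (named integer vector of peaks surviving each
#'   detection stage).
#' @export
extract_ppg_peaks <- function(raw, cfg = ppg_config(), verbose = FALSE) {
  stopifnot(inherits(raw, "frame_series"))
  if (diff(range(raw$times)) < 10)
    stop("recording shorter than 10 s", call. = FALSE)
  sig <- regularize_frames(raw)
  if (cfg$invert_luminosity) sig$values <- -sig$values
  sig <- bandpass_filter(sig, cfg)
  sig <- smooth_signal(sig, cfg)
  sig <- resample_cubic_spline(sig, cfg)
  pk0 <- detect_local_maxima(sig)
  # numerical floor: a flat recording leaves only arithmetic residue after
  # filtering; its maxima are not pulses
  floor_prom <- 1e-9 * max(1, max(abs(raw$values)))
  pk0 <- subset_peaks(pk0, pk0$prominences > floor_prom)
  pk1 <- prominence_filter_global(pk0, cfg)
  pk2 <- prominence_filter_window(pk1, cfg)
  counts <- c(detected = length(pk0), global_filter = length(pk1),
              window_filter = length(pk2))
  if (verbose)
    message(sprintf("ppg peaks: detected %d -> global %d -> window %d",
                    counts[1], counts[2], counts[3]))
  attr(pk2, "stage_counts") <- counts
  pk2
}
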
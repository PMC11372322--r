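#' Time-stamped frame-luminosity series (raw camera PPG)
#'
#' Container for a raw photoplethysmography recording as produced by averaging
#' the pixel luminosity of successive camera frames: one value per frame, with
#' its capture timestamp.
#'
#' @param times Numeric vector of frame timestamps in seconds, strictly
#'   increasing, nominally `1/nominal_rate` apart.
#' @param values Numeric vector of per-frame mean luminosities (arbitrary
#'   units), same length as `times`.
#' @param nominal_rate Nominal frame rate in frames/s (default 30).
#' @return An object of class `frame_series` with fields `times`, `values`
#'   and `nominal_rate`.
#' @seealso [average_frame_luminosity()], [extract_ppg_peaks()]
#' @export
frame_series <- function(times, values, nominal_rate = 30) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a frame series needs at least 2 frames", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("frame times and luminosities must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  if (!is.numeric(nominal_rate) || nominal_rate <= 0)
    stop("`nominal_rate` must be a positive frame rate", call. = FALSE)
  structure(list(times = times, values = values,
                 nominal_rate = as.numeric(nominal_rate)),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames, %.1f s @ %g fps nominal\n",
              length(x$times), diff(range(x$times)), x$nominal_rate))
  invisible(x)
}

#' Uniformly sampled one-dimensional signal
#'
#' @param values Numeric vector of samples (finite).
#' @param rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @return An object of class `uniform_signal`.
#' @export
uniform_signal <- function(values, rate, start_time = 0) {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive sampling rate in Hz", call. = FALSE)
  if (any(!is.finite(values)))
    stop("signal values must be finite", call. = FALSE)
  structure(list(start_time = as.numeric(start_time),
                 rate = as.numeric(rate), values = values),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %d samples @ %g Hz, t0 = %.3f s\n",
              length(x$values), x$rate, x$start_time))
  invisible(x)
}

#' Sample times of a uniform signal
#' @param signal A [uniform_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(signal) {
  signal$start_time + (seq_along(signal$values) - 1L) / signal$rate
}

#' Set of detected local maxima
#'
#' @param peak_times Peak times in seconds, strictly increasing.
#' @param peak_indices 1-based sample indices into the source signal.
#' @param prominences Topographic prominences (signal units, >= 0).
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(peak_times, peak_indices, prominences) {
  peak_times <- as.numeric(peak_times)
  peak_indices <- as.integer(peak_indices)
  prominences <- as.numeric(prominences)
  n <- length(peak_times)
  if (length(peak_indices) != n || length(prominences) != n)
    stop("peak fields must have equal length", call. = FALSE)
  if (n > 1L && any(diff(peak_times) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  if (any(prominences < 0))
    stop("prominences must be non-negative", call. = FALSE)
  structure(list(peak_times = peak_times, peak_indices = peak_indices,
                 prominences = prominences),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks", length(x$peak_times)))
  if (length(x$peak_times))
    cat(sprintf(", t in [%.3f, %.3f] s", min(x$peak_times), max(x$peak_times)))
  cat("\n")
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$peak_times)

#' Average per-frame pixel luminosity into a frame series
#'
#' Collapses a sequence of camera frames (2-D pixel intensity matrices) to a
#' single mean-luminosity value per frame, paired with its timestamp.  This is
#' the raw PPG signal: pulsatile blood volume modulates the light absorbed at
#' the fingertip, so the frame mean carries the pulse waveform.
#'
#' @param frames List of numeric matrices (or vectors), one per frame; each
#'   must be non-empty.
#' @param timestamps Capture times in seconds, strictly increasing, one per
#'   frame.
#' @param nominal_rate Nominal frame rate in frames/s (default 30).
#' @return A [frame_series()].
#' @export
average_frame_luminosity <- function(frames, timestamps, nominal_rate = 30) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of pixel arrays", call. = FALSE)
  if (length(timestamps) != length(frames))
    stop("`timestamps` must match `frames` in length", call. = FALSE)
  vals <- vapply(frames, function(f) {
    if (length(f) == 0L) stop("empty frame encountered", call. = FALSE)
    mean(as.numeric(f))
  }, numeric(1))
  frame_series(timestamps, vals, nominal_rate = nominal_rate)
}

#' Regularise a frame series onto its nominal uniform grid
#'
#' The digital filters downstream require uniform sampling.  Frame timestamps
#' may jitter slightly; when the worst-case deviation of the inter-frame
#' spacing from the nominal period stays below `max_jitter_fraction` of that
#' period, the series is treated as uniform at the nominal rate starting at
#' its first timestamp.  Larger jitter is an error rather than something to
#' silently interpolate over.
#'
#' @param frames A [frame_series()].
#' @param max_jitter_fraction Maximum tolerated deviation of frame spacing
#'   from the nominal period, as a fraction of the period (default 0.2).
#' @return A [uniform_signal()] at `frames$nominal_rate`.
#' @export
regularize_frames <- function(frames, max_jitter_fraction = 0.2) {
  stopifnot(inherits(frames, "frame_series"))
  period <- 1 / frames$nominal_rate
  jitter <- max(abs(diff(frames$times) - period))
  if (jitter >= max_jitter_fraction * period)
    stop(sprintf(paste0("frame timing jitter (%.1f ms) exceeds %.0f%% of the ",
                        "nominal frame period; cannot treat as uniform"),
                 1000 * jitter, 100 * max_jitter_fraction), call. = FALSE)
  uniform_signal(frames$values, rate = frames$nominal_rate,
                 start_time = frames$times[1])
}
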
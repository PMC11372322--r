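#' Configuration of the ECG R-wave detector
#'
#' @param expected_rate Expected ECG sampling rate, Hz (default 500).
#' @param highpass_hz Lower corner of the QRS emphasis band, removing
#'   baseline wander and P/T content before peak picking (default 5 Hz).
#' @param lowpass_hz Upper corner of the QRS emphasis band, suppressing
#'   wideband measurement noise (default 25 Hz; QRS energy concentrates
#'   below this).
#' @param refractory_ms Minimum separation between accepted R-peaks; of two
#'   peaks closer than this, the larger survives (default 250 ms, i.e. a
#'   240 bpm ceiling).
#' @param prominence_fraction Fraction of the median candidate prominence an
#'   R-peak must exceed (default 0.5).
#' @param candidate_fraction Fraction of the maximum prominence used to gate
#'   candidates before the median rule; keeps the median from being dragged
#'   to the noise floor by the many tiny maxima broadband noise creates.
#' @return A list of class `ecg_config`.
#' @export
ecg_config <- function(expected_rate = 500, highpass_hz = 5,
                       lowpass_hz = 25, refractory_ms = 250,
                       prominence_fraction = 0.5,
                       candidate_fraction = 0.25) {
  if (expected_rate <= 100)
    stop("`expected_rate` must exceed 100 Hz", call. = FALSE)
  if (refractory_ms <= 0)
    stop("`refractory_ms` must be positive", call. = FALSE)
  if (lowpass_hz <= highpass_hz)
    stop("`lowpass_hz` must exceed `highpass_hz`", call. = FALSE)
  structure(list(expected_rate = expected_rate, highpass_hz = highpass_hz,
                 lowpass_hz = lowpass_hz, refractory_ms = refractory_ms,
                 prominence_fraction = prominence_fraction,
                 candidate_fraction = candidate_fraction),
            class = "ecg_config")
}

#' Detect R-wave apices in an ECG signal
#'
#' A deliberately simple, fully deterministic detector adequate for clean
#' laboratory ECG: zero-phase bandpass onto the QRS energy band
#' (`highpass_hz`--`lowpass_hz`), neighbour-comparison local maxima,
#' a prominence gate (`candidate_fraction` of the maximum prominence, then
#' `prominence_fraction` of the median candidate prominence), and a
#' refractory rule keeping the larger of any two peaks closer than
#' `refractory_ms`.  Thresholds are all relative, so the detector is
#' invariant to gain and offset of the recording.
#'
#' @param ecg A [uniform_signal()] of at least 10 s at >= 100 Hz.
#' @param cfg An [ecg_config()].
#' @return A [peak_set()] of R apex times; empty for a flat signal.
#' @export
detect_r_peaks <- function(ecg, cfg = ecg_config()) {
  stopifnot(inherits(ecg, "uniform_signal"))
  if (ecg$rate < 100)
    stop("ECG sampling rate must be >= 100 Hz", call. = FALSE)
  if (length(ecg$values) / ecg$rate < 10)
    stop("ECG recording shorter than 10 s", call. = FALSE)
  if (diff(range(ecg$values)) == 0)
    return(peak_set(numeric(0), integer(0), numeric(0)))
  bp <- signal::butter(2, c(cfg$highpass_hz, cfg$lowpass_hz) / (ecg$rate / 2),
                       type = "pass")
  x <- filtfilt_padded(bp, ecg$values - mean(ecg$values),
                       as.integer(ceiling(3 * ecg$rate / cfg$highpass_hz)))
  flt <- uniform_signal(x, rate = ecg$rate, start_time = ecg$start_time)
  pk <- detect_local_maxima(flt)
  if (length(pk) == 0L) return(pk)
  pk <- subset_peaks(pk, pk$prominences >
                           cfg$candidate_fraction * max(pk$prominences))
  pk <- subset_peaks(pk, pk$prominences >
                           cfg$prominence_fraction * stats::median(pk$prominences))
  # refractory: repeatedly drop the smaller of the closest offending pair
  refr <- cfg$refractory_ms / 1000
  repeat {
    if (length(pk) < 2L) break
    gaps <- diff(pk$peak_times)
    bad <- which(gaps < refr)
    if (length(bad) == 0L) break
    drop <- vapply(bad, function(i) {
      amp <- x[pk$peak_indices[c(i, i + 1L)]]
      if (amp[1] >= amp[2]) i + 1L else i
    }, integer(1))
    pk <- subset_peaks(pk, -unique(drop))
  }
  pk
}

#' R-R intervals from detected R-peaks
#'
#' Identical contract to [compute_intervals()]: successive differences in ms,
#' stamped with the ending R time.
#'
#' @param peaks A [peak_set()] of R-peaks (>= 2).
#' @return An [interval_series()].
#' @export
compute_rr_intervals <- function(peaks) compute_intervals(peaks)

#' Flag possibly ectopic beats for human review
#'
#' Compares every interval with the running median of the 11 nearest
#' intervals ([stats::runmed()], median end rule) and flags, without
#' removing, those deviating by more than `tolerance_fraction` of the local
#' median.  The rule is scale invariant: rescaling all intervals changes no
#' flags.
#'
#' @param series An [interval_series()] with >= 11 intervals.
#' @param tolerance_fraction Maximum tolerated relative deviation from the
#'   running median (default 0.3).
#' @return A list with elements `series` (unchanged), `flagged` (data frame
#'   of `beat_time_s`, `interval_ms`, `local_median_ms`, `deviation` for the
#'   flagged beats) and `n_flagged`.
#' @export
screen_ectopy <- function(series, tolerance_fraction = 0.3) {
  stopifnot(inherits(series, "interval_series"))
  x <- series$intervals
  if (length(x) < 11L)
    stop("ectopy screening needs at least 11 intervals", call. = FALSE)
  med <- as.numeric(stats::runmed(x, k = 11L, endrule = "median"))
  dev <- abs(x - med) / med
  hit <- which(dev > tolerance_fraction)
  list(series = series,
       flagged = data.frame(beat_time_s = series$beat_times[hit],
                            interval_ms = x[hit],
                            local_median_ms = med[hit],
                            deviation = dev[hit]),
       n_flagged = length(hit))
}
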
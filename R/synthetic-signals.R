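#' Configuration of the paired ECG/PPG recording simulator
#'
#' Defaults emulate a 5-minute seated resting recording from a young healthy
#' adult: mean heart period 857 ms (70 bpm), SDNN near 73 ms dominated by
#' respiratory sinus arrhythmia at a spontaneous breathing rate of 0.25 Hz,
#' a pulse transit delay of 250 ms between the R-wave and the fingertip
#' pulse, a dicrotic (diastolic) secondary wave at 40% relative amplitude,
#' slow baseline drift of the luminosity, and optional motion artifacts.
#'
#' The RR variability splits as `sdnn^2 = rsa_amplitude^2/2 + rr_noise_sd^2`;
#' the default 102 ms RSA amplitude + 10 ms white beat noise give SDNN of
#' about 73 ms while keeping clean beat-to-beat changes below the 20%
#' physiological-implausibility threshold, as real artifact-free resting
#' recordings do.
#'
#' @param duration_s Recording length in seconds (default 300).
#' @param mean_rr_ms Mean heart period in ms (default 857).
#' @param rr_noise_sd_ms SD of white per-beat timing noise, ms.
#' @param rsa_amplitude_ms Amplitude of the respiratory modulation of RR, ms.
#' @param rsa_freq_hz Breathing frequency, Hz (default 0.25).
#' @param ecg_rate_hz ECG sampling rate (default 500).
#' @param ppg_rate_hz PPG frame rate (default 30).
#' @param transit_delay_ms R-wave to fingertip-pulse delay, ms (default 250).
#' @param dicrotic_rel_amplitude Dicrotic wave amplitude relative to the
#'   systolic wave (default 0.4); placed at `dicrotic_frac_rr` of the local
#'   RR after the systolic peak.
#' @param dicrotic_frac_rr Dicrotic delay as a fraction of the local RR
#'   (default 0.35).
#' @param pulse_rise_s,pulse_decay_s Width (Gaussian sigma, s) of the
#'   systolic upstroke and decay halves of the pulse waveform.
#' @param dicrotic_width_s Width (sigma, s) of the dicrotic wave.
#' @param ppg_noise_sd Additive luminosity noise SD (pulse amplitude is 1).
#' @param drift_amplitude,drift_freq_hz Baseline luminosity drift sinusoid.
#' @param ecg_noise_sd Additive ECG noise SD (R amplitude is 1).
#' @param timestamp_jitter_s SD of frame timestamp jitter, s.
#' @param artifact_fraction Fraction of beats disturbed by
#'   [inject_artifacts()].
#' @param seed Integer seed; every generator is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 300, mean_rr_ms = 857,
                       rr_noise_sd_ms = 10, rsa_amplitude_ms = 102,
                       rsa_freq_hz = 0.25, ecg_rate_hz = 500,
                       ppg_rate_hz = 30, transit_delay_ms = 250,
                       dicrotic_rel_amplitude = 0.4, dicrotic_frac_rr = 0.35,
                       pulse_rise_s = 0.075, pulse_decay_s = 0.085,
                       dicrotic_width_s = 0.05, ppg_noise_sd = 0.02,
                       drift_amplitude = 0.5, drift_freq_hz = 0.05,
                       ecg_noise_sd = 0, timestamp_jitter_s = 0,
                       artifact_fraction = 0, seed = NULL) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (mean_rr_ms <= 300 || mean_rr_ms >= 3000)
    stop("`mean_rr_ms` must lie in (300, 3000)", call. = FALSE)
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    stop("`artifact_fraction` must lie in [0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

seeded <- function(seed, offset) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147480000L + offset)
}

#' Generate a ground-truth RR series and beat times
#'
#' Beat periods follow
#' `RR_i = mean_rr + rsa_amplitude * sin(2 pi rsa_freq t_i) + eps_i` with
#' `eps_i ~ N(0, rr_noise_sd^2)`, truncated to the physiological range
#' (300, 3000) ms; beat times are the cumulative sums.  The first beat is
#' placed at 0.5 s and the last at least ~1.2 s before the end of the
#' record, so every ECG complex and every (transit-delayed) PPG pulse lies
#' wholly inside the recording and the true beat count is well defined.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `ground_truth`: `rr_ms` (n - 1 intervals),
#'   `ecg_beat_times_s` (n), `ppg_peak_times_s` (= ECG times + transit
#'   delay), `artifact_flags` (per-interval, all `"clean"` here).
#' @export
generate_rr_series <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seeded(cfg$seed, 0L)
  t_end <- cfg$duration_s - 1.2
  t <- 0.5
  beats <- t
  rr <- numeric(0)
  repeat {
    r <- cfg$mean_rr_ms + cfg$rsa_amplitude_ms * sin(2 * pi * cfg$rsa_freq_hz * t) +
      stats::rnorm(1, 0, cfg$rr_noise_sd_ms)
    r <- min(max(r, 300 + 1e-9), 3000 - 1e-9)
    if (t + r / 1000 > t_end) break
    t <- t + r / 1000
    beats <- c(beats, t)
    rr <- c(rr, r)
  }
  if (length(beats) < 2L)
    stop("configuration yields fewer than 2 beats", call. = FALSE)
  structure(list(rr_ms = rr, ecg_beat_times_s = beats,
                 ppg_peak_times_s = beats + cfg$transit_delay_ms / 1000,
                 artifact_flags = rep("clean", length(rr))),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats, mean RR %.1f ms, SDNN %.1f ms, %d artifact intervals\n",
              length(x$ecg_beat_times_s), mean(x$rr_ms), stats::sd(x$rr_ms),
              sum(x$artifact_flags != "clean")))
  invisible(x)
}

# add bump(t - center) to sig over center +/- span (s); sig sampled at rate
add_bump <- function(values, rate, t0, center, span, f) {
  i0 <- max(1L, floor((center - span - t0) * rate) + 1L)
  i1 <- min(length(values), ceiling((center + span - t0) * rate) + 1L)
  if (i0 > i1) return(values)
  tt <- t0 + (i0:i1 - 1L) / rate
  values[i0:i1] <- values[i0:i1] + f(tt - center)
  values
}

#' Synthesise a reference ECG from ground-truth beat times
#'
#' Each beat contributes a narrow Gaussian R spike (unit amplitude, sigma
#' 6 ms) plus smaller, broader P and T waves; optional additive Gaussian
#' noise (`cfg$ecg_noise_sd`).  Sampled at `cfg$ecg_rate_hz` from time 0.
#'
#' @param gt A [generate_rr_series()] result.
#' @param cfg A [sim_config()].
#' @return A [uniform_signal()].
#' @export
synthesize_ecg <- function(gt, cfg = sim_config()) {
  stopifnot(inherits(gt, "ground_truth"))
  seeded(cfg$seed, 1L)
  n <- floor(cfg$duration_s * cfg$ecg_rate_hz) + 1L
  x <- numeric(n)
  for (b in gt$ecg_beat_times_s) {
    x <- add_bump(x, cfg$ecg_rate_hz, 0, b, 0.03,
                  function(u) exp(-u^2 / (2 * 0.006^2)))
    x <- add_bump(x, cfg$ecg_rate_hz, 0, b - 0.18, 0.16,
                  function(u) 0.10 * exp(-u^2 / (2 * 0.04^2)))
    x <- add_bump(x, cfg$ecg_rate_hz, 0, b + 0.28, 0.24,
                  function(u) 0.18 * exp(-u^2 / (2 * 0.06^2)))
  }
  if (cfg$ecg_noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$ecg_noise_sd)
  uniform_signal(x, rate = cfg$ecg_rate_hz, start_time = 0)
}

#' Synthesise a camera-PPG frame-luminosity series from ground truth
#'
#' Each beat contributes a systolic pulse (asymmetric two-half-Gaussian bump,
#' unit amplitude, peaking at the beat time plus the transit delay) and a
#' dicrotic wave (`dicrotic_rel_amplitude`, at `dicrotic_frac_rr` of the
#' local RR after the systolic peak).  The waveform is *subtracted* from a
#' constant luminosity of 100: more blood absorbs more light, so pulses are
#' luminosity dips (the extraction pipeline negates the signal by default).
#' Baseline drift (`drift_amplitude` at `drift_freq_hz`) and white noise are
#' added, and frame timestamps can jitter.
#'
#' The pulse morphology defaults (rise 75 ms / decay 85 ms sigma) are chosen
#' so that the 0.75--3 Hz zero-phase bandpass of the extraction pipeline
#' displaces the systolic maximum by less than one resampled sample; a more
#' asymmetric waveform would make the generator's own peak-time ground truth
#' unusable for timing checks.
#'
#' @param gt A [generate_rr_series()] result.
#' @param cfg A [sim_config()].
#' @return A [frame_series()] at `cfg$ppg_rate_hz`.
#' @export
synthesize_ppg <- function(gt, cfg = sim_config()) {
  stopifnot(inherits(gt, "ground_truth"))
  seeded(cfg$seed, 2L)
  nf <- floor(cfg$duration_s * cfg$ppg_rate_hz) + 1L
  times <- (0:(nf - 1L)) / cfg$ppg_rate_hz
  if (cfg$timestamp_jitter_s > 0) {
    times <- times + stats::rnorm(nf, 0, cfg$timestamp_jitter_s)
    times <- sort(times)
    times <- times - times[1]
  }
  pulse <- function(u) ifelse(u < 0, exp(-u^2 / (2 * cfg$pulse_rise_s^2)),
                              exp(-u^2 / (2 * cfg$pulse_decay_s^2)))
  x <- numeric(nf)
  nb <- length(gt$ppg_peak_times_s)
  local_rr <- c(gt$rr_ms, gt$rr_ms[length(gt$rr_ms)]) / 1000
  for (i in seq_len(nb)) {
    p <- gt$ppg_peak_times_s[i]
    x <- add_bump(x, cfg$ppg_rate_hz, 0, p, 5 * cfg$pulse_decay_s, pulse)
    if (cfg$dicrotic_rel_amplitude > 0)
      x <- add_bump(x, cfg$ppg_rate_hz, 0, p + cfg$dicrotic_frac_rr * local_rr[i],
                    4 * cfg$dicrotic_width_s,
                    function(u) cfg$dicrotic_rel_amplitude *
                      exp(-u^2 / (2 * cfg$dicrotic_width_s^2)))
  }
  lum <- 100 - x +
    cfg$drift_amplitude * sin(2 * pi * cfg$drift_freq_hz * times)
  if (cfg$ppg_noise_sd > 0) lum <- lum + stats::rnorm(nf, 0, cfg$ppg_noise_sd)
  frame_series(times, lum, nominal_rate = cfg$ppg_rate_hz)
}

#' Inject labelled beat artifacts into a ground truth
#'
#' Disturbs a seeded random selection of `artifact_fraction` of the
#' intervals, each with one of: a missed beat (two adjacent RR merged), a
#' double detection (one RR split in 0.45/0.55 halves), or a spike (RR
#' scaled by 0.4 or 2.5).  Beat times are rebuilt as cumulative sums so the
#' beat-time/RR consistency invariant still holds, and every affected
#' interval is labelled in `artifact_flags`.
#'
#' @param gt A [generate_rr_series()] result.
#' @param cfg A [sim_config()] with `artifact_fraction > 0` (0 returns `gt`
#'   unchanged).
#' @return A modified `ground_truth` with labelled `artifact_flags`.
#' @export
inject_artifacts <- function(gt, cfg = sim_config()) {
  stopifnot(inherits(gt, "ground_truth"))
  if (cfg$artifact_fraction == 0) return(gt)
  seeded(cfg$seed, 3L)
  rr <- gt$rr_ms
  flags <- gt$artifact_flags
  n <- length(rr)
  n_a <- max(1L, round(cfg$artifact_fraction * n))
  picks <- sort(sample.int(n - 1L, n_a), decreasing = TRUE)
  kinds <- sample(c("merge", "split", "spike_low", "spike_high"),
                  n_a, replace = TRUE)
  for (j in seq_len(n_a)) {
    i <- picks[j]
    switch(kinds[j],
      merge = {
        rr <- c(rr[seq_len(i - 1L)], rr[i] + rr[i + 1L],
                rr[seq_len(n - i - 1L) + i + 1L])
        flags <- c(flags[seq_len(i - 1L)], "missed_beat",
                   flags[seq_len(n - i - 1L) + i + 1L])
      },
      split = {
        rr <- c(rr[seq_len(i - 1L)], 0.45 * rr[i], 0.55 * rr[i],
                rr[seq_len(n - i) + i])
        flags <- c(flags[seq_len(i - 1L)], "double_detection",
                   "double_detection", flags[seq_len(n - i) + i])
      },
      spike_low = {
        rr[i] <- 0.4 * rr[i]
        flags[i] <- "spike"
      },
      spike_high = {
        rr[i] <- 2.5 * rr[i]
        flags[i] <- "spike"
      })
    n <- length(rr)
  }
  beats <- gt$ecg_beat_times_s[1] + c(0, cumsum(rr)) / 1000
  structure(list(rr_ms = rr, ecg_beat_times_s = beats,
                 ppg_peak_times_s = beats + cfg$transit_delay_ms / 1000,
                 artifact_flags = flags),
            class = "ground_truth")
}

#' Simulate one paired recording (ground truth + ECG + PPG)
#'
#' Convenience wrapper: [generate_rr_series()], optional
#' [inject_artifacts()], then [synthesize_ecg()] and [synthesize_ppg()].
#'
#' @param cfg A [sim_config()].
#' @return A list `truth`, `ecg` ([uniform_signal()]), `ppg`
#'   ([frame_series()]), `config`.
#' @export
simulate_recording <- function(cfg = sim_config()) {
  gt <- generate_rr_series(cfg)
  gt <- inject_artifacts(gt, cfg)
  list(truth = gt, ecg = synthesize_ecg(gt, cfg),
       ppg = synthesize_ppg(gt, cfg), config = cfg)
}

#' Simulate a cohort of paired recordings
#'
#' Draws per-subject mean heart periods uniformly from `mean_rr_range`
#' (default 682--1017 ms, i.e. roughly 59--88 bpm) and per-subject SDNN
#' targets from a normal distribution centred on `sdnn_mean` ms (SD
#' `sdnn_sd`, truncated to [25, 130] ms); the subject's RSA amplitude is set
#' to realise the target given the white-noise floor.  Each subject is
#' generated with a seed derived from `seed`, so the cohort is bit-for-bit
#' reproducible.
#'
#' @param n_subjects Number of subjects (>= 2; the emulated cohort had 14).
#' @param cfg Base [sim_config()] shared by all subjects.
#' @param mean_rr_range Range (ms) of per-subject mean heart periods.
#' @param sdnn_mean,sdnn_sd Cohort distribution of the per-subject SDNN
#'   target (ms).
#' @param seed Integer seed.
#' @return List of per-subject lists as in [simulate_recording()].
#' @export
simulate_cohort <- function(n_subjects = 14, cfg = sim_config(),
                            mean_rr_range = c(682, 1017),
                            sdnn_mean = 73, sdnn_sd = 23, seed = 1) {
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  seeded(seed, 4L)
  mrr <- stats::runif(n_subjects, mean_rr_range[1], mean_rr_range[2])
  sdnn <- pmin(pmax(stats::rnorm(n_subjects, sdnn_mean, sdnn_sd), 25), 130)
  lapply(seq_len(n_subjects), function(i) {
    scfg <- cfg
    scfg$mean_rr_ms <- mrr[i]
    scfg$rsa_amplitude_ms <-
      sqrt(2 * max(sdnn[i]^2 - cfg$rr_noise_sd_ms^2, 1))
    scfg$seed <- (if (is.null(seed)) 0L else as.integer(seed) %% 2000000L) * 1000L + i
    simulate_recording(scfg)
  })
}
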
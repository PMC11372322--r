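cfg30 <- ppg_config()

test_that("bandpass removes DC and passes the pulse band", {
  fs <- 30
  const <- uniform_signal(rep(5, 60 * fs), fs)
  expect_lt(max(abs(bandpass_filter(const, cfg30)$values)), 1e-6)

  t <- (0:(60 * fs - 1)) / fs
  inband <- uniform_signal(sin(2 * pi * 1.5 * t), fs)
  out <- bandpass_filter(inband, cfg30)
  interior <- out$values[(10 * fs):(50 * fs)]
  expect_lt(abs(max(abs(interior)) - 1), 0.05)

  t2 <- (0:(120 * fs - 1)) / fs
  slow <- uniform_signal(sin(2 * pi * 0.1 * t2), fs)
  out2 <- bandpass_filter(slow, cfg30)
  expect_lt(max(abs(out2$values[(30 * fs):(90 * fs)])), 0.1)
})

test_that("bandpass and smoothing preserve length, rate and start time", {
  sig <- uniform_signal(rnorm(600), 30, start_time = 2.5)
  for (f in list(bandpass_filter, smooth_signal)) {
    out <- f(sig, cfg30)
    expect_equal(length(out$values), 600)
    expect_equal(out$rate, 30)
    expect_equal(out$start_time, 2.5)
  }
  expect_error(bandpass_filter(uniform_signal(rnorm(10), 30), cfg30),
               "too short")
})

test_that("smoothing is unit-sum, linear, and affine-preserving inside", {
  expect_equal(smooth_signal(uniform_signal(rep(3.2, 50), 30), cfg30)$values,
               rep(3.2, 50))
  # impulse response reproduces the scaled window
  imp <- rep(0, 51); imp[26] <- 1
  out <- smooth_signal(uniform_signal(imp, 30), cfg30)$values
  hann5 <- c(0, 0.5, 1, 0.5, 0); hann5 <- hann5 / sum(hann5)
  expect_equal(out[24:28], hann5, tolerance = 1e-12)
  # linearity
  set.seed(3)
  x <- rnorm(100); y <- rnorm(100)
  sm <- function(v) smooth_signal(uniform_signal(v, 30), cfg30)$values
  expect_equal(sm(2 * x - 3 * y), 2 * sm(x) - 3 * sm(y), tolerance = 1e-9)
  # interior of a ramp unchanged
  ramp <- seq(0, 10, length.out = 100)
  expect_equal(sm(ramp)[3:98], ramp[3:98], tolerance = 1e-9)
  # flat window variant is a moving average
  cfg_flat <- ppg_config(smooth_window_shape = "flat")
  expect_equal(smooth_signal(uniform_signal(x, 30), cfg_flat)$values[50],
               mean(x[48:52]), tolerance = 1e-12)
  expect_error(smooth_signal(uniform_signal(rnorm(3), 30), cfg30), "longer")
})

test_that("cubic spline resampling reproduces cubics and interpolates", {
  fs <- 30
  t <- (0:(10 * fs)) / fs
  p <- t^3 - 2 * t + 1
  out <- resample_cubic_spline(uniform_signal(p, fs), cfg30)
  tout <- signal_times(out)
  expect_equal(length(out$values), floor(10 * 180) + 1)
  expect_lt(max(abs(out$values - (tout^3 - 2 * tout + 1))), 1e-9)
  # interpolation at coincident grid times (every 6th output sample)
  expect_equal(out$values[seq(1, length(out$values), by = 6)], p,
               tolerance = 1e-9)
  # analytic sine oracle
  s <- sin(2 * pi * t)
  outs <- resample_cubic_spline(uniform_signal(s, fs), cfg30)
  expect_lt(max(abs(outs$values - sin(2 * pi * signal_times(outs)))), 1e-3)
  expect_error(resample_cubic_spline(uniform_signal(1:3, 30), cfg30),
               "at least 4")
})

test_that("neighbour-comparison peaks and prominences match brute force", {
  expect_length(detect_local_maxima(uniform_signal(1:10, 1)), 0)
  pk <- detect_local_maxima(uniform_signal(c(0, 1, 0), 1))
  expect_equal(pk$peak_indices, 2L)
  expect_equal(pk$prominences, 1)
  # plateau: first sample wins
  pk2 <- detect_local_maxima(uniform_signal(c(0, 2, 2, 2, 0), 1))
  expect_equal(pk2$peak_indices, 2L)

  for (seed in 1:100) {
    set.seed(seed)
    x <- cumsum(rnorm(200))
    pk <- detect_local_maxima(uniform_signal(x, 10))
    expect_identical(pk$peak_indices, as.integer(oracle_local_maxima(x)))
    expect_equal(pk$prominences,
                 vapply(pk$peak_indices, function(i) oracle_prominence(x, i),
                        numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("global prominence filter keeps peaks above 30% of the mean", {
  mk <- function(prom) peak_set(seq_along(prom), seq_along(prom), prom)
  out <- prominence_filter_global(mk(c(10, 10, 10, 1)), cfg30)
  expect_equal(out$prominences, c(10, 10, 10))
  expect_length(prominence_filter_global(mk(rep(4, 6)), cfg30), 6)
  expect_length(prominence_filter_global(mk(5), cfg30), 1)
})

test_that("windowed prominence filter follows the clamped 5-peak rule", {
  mk <- function(prom) peak_set(seq_along(prom), seq_along(prom), prom)
  out <- prominence_filter_window(mk(c(10, 10, 10, 10, 2)), cfg30)
  expect_equal(out$prominences, c(10, 10, 10, 10))
  expect_length(prominence_filter_window(mk(rep(7, 9)), cfg30), 9)
  alt <- rep(c(10, 2), 10)
  out2 <- prominence_filter_window(mk(alt), cfg30)
  expect_equal(out2$peak_indices,
               as.integer(oracle_window_filter(alt, 0.75, 5)))
})

test_that("prominence filters only remove peaks and keep times", {
  set.seed(7)
  for (rep_i in 1:20) {
    x <- cumsum(rnorm(300))
    pk <- detect_local_maxima(uniform_signal(x, 10))
    for (f in list(prominence_filter_global, prominence_filter_window)) {
      out <- f(pk, cfg30)
      expect_true(all(out$peak_times %in% pk$peak_times))
      expect_true(all(out$peak_indices %in% pk$peak_indices))
    }
    expect_equal(prominence_filter_global(pk, cfg30)$peak_indices,
                 pk$peak_indices[oracle_global_filter(pk$prominences, 0.3)])
    expect_equal(prominence_filter_window(pk, cfg30)$peak_indices,
                 pk$peak_indices[oracle_window_filter(pk$prominences, 0.75, 5)])
  }
})

test_that("the full extraction chain recovers clean synthetic beats", {
  cfg <- sim_config(seed = 5, duration_s = 60, ppg_noise_sd = 0,
                    drift_amplitude = 0, dicrotic_rel_amplitude = 0,
                    mean_rr_ms = 1000, rsa_amplitude_ms = 0,
                    rr_noise_sd_ms = 0)
  rec <- simulate_recording(cfg)
  pk <- extract_ppg_peaks(rec$ppg)
  expect_equal(length(pk), length(rec$truth$ppg_peak_times_s))
  expect_lt(max(abs(pk$peak_times - rec$truth$ppg_peak_times_s)), 2 / 180)

  # dicrotic waves at 40% amplitude are rejected by the validity filters
  cfg2 <- sim_config(seed = 6, duration_s = 60, ppg_noise_sd = 0,
                     drift_amplitude = 0, dicrotic_rel_amplitude = 0.4)
  rec2 <- simulate_recording(cfg2)
  pk2 <- extract_ppg_peaks(rec2$ppg)
  counts <- attr(pk2, "stage_counts")
  expect_gt(counts["detected"], length(rec2$truth$ppg_peak_times_s))
  expect_equal(length(pk2), length(rec2$truth$ppg_peak_times_s))

  # constant luminosity yields no peaks at all
  flat <- frame_series((0:900) / 30, rep(80, 901))
  expect_length(extract_ppg_peaks(flat), 0)
  expect_error(extract_ppg_peaks(frame_series((0:60) / 30, rnorm(61))),
               "10 s")
})
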
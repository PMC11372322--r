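test_that("RR generation hits its statistical targets", {
  # no variability: perfectly periodic
  cfg0 <- sim_config(seed = 81, duration_s = 60, rr_noise_sd_ms = 0,
                     rsa_amplitude_ms = 0, mean_rr_ms = 1000)
  gt0 <- generate_rr_series(cfg0)
  expect_true(all(abs(gt0$rr_ms - 1000) < 1e-9))
  expect_equal(diff(gt0$ecg_beat_times_s), gt0$rr_ms / 1000,
               tolerance = 1e-9)
  # white-noise SD recovered (many beats)
  cfgn <- sim_config(seed = 82, duration_s = 8000, rr_noise_sd_ms = 50,
                     rsa_amplitude_ms = 0, mean_rr_ms = 800)
  gtn <- generate_rr_series(cfgn)
  expect_gt(length(gtn$rr_ms), 5000)
  expect_lt(abs(sd(gtn$rr_ms) - 50) / 50, 0.03)
  # sinusoidal modulation: SD ~ A / sqrt(2)
  cfgr <- sim_config(seed = 83, duration_s = 2000, rr_noise_sd_ms = 0,
                     rsa_amplitude_ms = 80)
  gtr <- generate_rr_series(cfgr)
  expect_lt(abs(sd(gtr$rr_ms) - 80 / sqrt(2)) / (80 / sqrt(2)), 0.05)
  expect_error(generate_rr_series(sim_config(duration_s = 2)), "2 beats")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 84, duration_s = 40, ecg_noise_sd = 0.05,
                    artifact_fraction = 0.05)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$truth, r2$truth)
  expect_identical(r1$ecg$values, r2$ecg$values)
  expect_identical(r1$ppg$values, r2$ppg$values)
  coh1 <- simulate_cohort(3, sim_config(duration_s = 30), seed = 9)
  coh2 <- simulate_cohort(3, sim_config(duration_s = 30), seed = 9)
  expect_identical(coh1[[2]]$ppg$values, coh2[[2]]$ppg$values)
})

test_that("synthetic ECG peaks sit at the ground-truth beat times", {
  cfg <- sim_config(seed = 85, duration_s = 40)
  gt <- generate_rr_series(cfg)
  ecg <- synthesize_ecg(gt, cfg)
  tt <- signal_times(ecg)
  for (b in gt$ecg_beat_times_s[3:10]) {
    win <- which(abs(tt - b) <= 0.2)
    expect_lte(abs(tt[win[which.max(ecg$values[win])]] - b), 1 / 500 + 1e-12)
  }
})

test_that("PPG synthesis exposes dicrotic waves and survives drift", {
  base <- list(seed = 86, duration_s = 60, ppg_noise_sd = 0,
               drift_amplitude = 0, mean_rr_ms = 900)
  cfg0 <- do.call(sim_config, c(base, dicrotic_rel_amplitude = 0))
  rec0 <- simulate_recording(cfg0)
  pk0 <- extract_ppg_peaks(rec0$ppg)
  expect_equal(length(pk0), length(rec0$truth$ppg_peak_times_s))

  cfgd <- do.call(sim_config, c(base, dicrotic_rel_amplitude = 0.4))
  recd <- simulate_recording(cfgd)
  pkd <- extract_ppg_peaks(recd$ppg)
  counts <- attr(pkd, "stage_counts")
  nb <- length(recd$truth$ppg_peak_times_s)
  expect_gt(counts["detected"], 1.5 * nb)   # raw maxima ~ 2x beats
  expect_equal(length(pkd), nb)

  # strong drift (10x pulse amplitude) is removed by the bandpass
  cfg_drift <- sim_config(seed = 87, duration_s = 60, ppg_noise_sd = 0,
                          drift_amplitude = 10, dicrotic_rel_amplitude = 0.4)
  rec_dr <- simulate_recording(cfg_drift)
  pk_dr <- extract_ppg_peaks(rec_dr$ppg)
  expect_equal(length(pk_dr), length(rec_dr$truth$ppg_peak_times_s))
})

test_that("artifact injection relabels and keeps time consistency", {
  cfg <- sim_config(seed = 88, duration_s = 300)
  gt <- generate_rr_series(cfg)
  expect_identical(inject_artifacts(gt, cfg), gt)   # fraction 0

  cfg5 <- sim_config(seed = 88, duration_s = 1000, artifact_fraction = 0.05)
  gt5 <- inject_artifacts(generate_rr_series(cfg5), cfg5)
  n_art <- sum(gt5$artifact_flags != "clean")
  n_beats <- length(generate_rr_series(cfg5)$rr_ms)
  # one pick yields 1 or 2 labelled intervals
  expect_gte(n_art, round(0.05 * n_beats))
  expect_lte(n_art, 2 * round(0.05 * n_beats))
  expect_equal(diff(gt5$ecg_beat_times_s), gt5$rr_ms / 1000,
               tolerance = 1e-9)
  expect_equal(gt5$ppg_peak_times_s - gt5$ecg_beat_times_s,
               rep(0.25, length(gt5$ecg_beat_times_s)))
})

test_that("merged beats are caught by the cleaning filters", {
  caught <- 0L; total <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(seed = 200 + seed, duration_s = 300,
                      artifact_fraction = 0.03)
    gt <- inject_artifacts(generate_rr_series(cfg), cfg)
    merged <- which(gt$artifact_flags == "missed_beat")
    if (!length(merged)) next
    cleaned <- clean_intervals(make_series(gt$rr_ms))
    caught <- caught + sum(cleaned$status[merged] != "valid")
    total <- total + length(merged)
  }
  expect_gt(total, 0)
  expect_gte(caught / total, 0.95)
})

test_that("cohort simulation spans the intended physiological ranges", {
  coh <- simulate_cohort(14, sim_config(duration_s = 30), seed = 4)
  mrr <- vapply(coh, function(s) mean(s$truth$rr_ms), numeric(1))
  expect_true(all(mrr > 600 & mrr < 1150))
  expect_true(mean(mrr) > 682 - 100 && mean(mrr) < 1017 + 100)
  expect_length(coh, 14)
})
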
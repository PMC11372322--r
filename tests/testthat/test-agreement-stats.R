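test_that("hrv_summary gives the sample mean and SD of valid intervals", {
  h <- hrv_summary(make_series(c(800, 900, 1000)))
  expect_equal(h$mean_pi, 900)
  expect_equal(h$sdnn, 100)
  expect_equal(hrv_summary(make_series(rep(750, 10)))$sdnn, 0)
  # only valid intervals count
  s <- make_series(c(800, 900, 1000, 2500))
  s$status[4] <- "rejected_quartile"
  expect_equal(hrv_summary(s)$n_beats, 3)
  # two-pass oracle + permutation invariance
  set.seed(71)
  x <- rnorm(1000, 857, 73)
  h2 <- hrv_summary(make_series(x))
  m <- sum(x) / 1000
  expect_equal(h2$mean_pi, m, tolerance = 1e-12)
  expect_equal(h2$sdnn, sqrt(sum((x - m)^2) / 999), tolerance = 1e-12)
  expect_equal(hrv_summary(make_series(sort(x)))$sdnn, h2$sdnn)
  expect_error(hrv_summary(make_series(800)), "at least 2")
})

test_that("pearson_cor matches the closed-form and handles exact fits", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  got <- pearson_cor(x, c(2, 1, 4, 3))
  ora <- oracle_pearson(x, c(2, 1, 4, 3))
  expect_equal(got$r, ora$r, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  expect_error(pearson_cor(x, rep(1, 4)), "zero-variance")
})

test_that("absolute-agreement ICC matches the ANOVA oracle", {
  x <- c(9, 10, 11, 14, 8, 12)
  expect_equal(icc_absolute_agreement(x, x)$icc, 1)
  expect_equal(icc_absolute_agreement(x, x)$ci_high, 1)
  tab <- icc_absolute_agreement(x, c(8, 11, 12, 13, 9, 11))
  expect_equal(tab$icc, oracle_icc_a1(x, c(8, 11, 12, 13, 9, 11)),
               tolerance = 1e-12)
  # a large constant offset destroys absolute agreement but not correlation
  off <- icc_absolute_agreement(x, x + 50)
  expect_equal(pearson_cor(x, x + 50)$r, 1)
  expect_lt(off$icc, 0.5)
  expect_equal(off$icc, oracle_icc_a1(x, x + 50), tolerance = 1e-12)
  # degenerate: no between-subject variance
  expect_warning(deg <- icc_absolute_agreement(rep(5, 4), rep(5, 4)), "ICC")
  expect_true(deg$degenerate)
  expect_equal(deg$icc, 0)
})

test_that("ICC confidence interval brackets the estimate", {
  set.seed(72)
  for (i in 1:20) {
    x <- rnorm(12, 850, 90)
    y <- x + rnorm(12, 2, 15)
    r <- icc_absolute_agreement(x, y)
    expect_lte(r$ci_low, r$icc)
    expect_gte(r$ci_high, r$icc)
    expect_lte(r$ci_high, 1)
  }
})

test_that("bland_altman computes bias, LoA and both bias tests", {
  set.seed(73)
  x <- rnorm(30, 850, 80)
  y <- x + rnorm(30, -1.5, 3)
  ba <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * sd(d))
  tt <- t.test(d)
  expect_equal(ba$fixed_bias_p, tt$p.value)
  fit <- summary(lm(d ~ I((x + y) / 2)))
  expect_equal(ba$prop_slope_b, unname(coef(fit)[2, 1]), tolerance = 1e-12)
  expect_equal(ba$prop_r2, fit$r.squared, tolerance = 1e-12)
  # antisymmetry under swap; R^2 invariant
  ba_sw <- bland_altman(y, x)
  expect_equal(ba_sw$mean_diff, -ba$mean_diff)
  expect_equal(ba_sw$prop_r2, ba$prop_r2, tolerance = 1e-12)
  # identical methods
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$mean_diff, ba0$sd_diff, ba0$loa_lower, ba0$loa_upper,
                 ba0$prop_slope_b), rep(0, 5))
  expect_error(bland_altman(x[1:2], y[1:2]), "3 pairs")
})

test_that("compare_methods runs the battery at both levels", {
  # single subject, PPG intervals exactly equal ECG intervals
  s <- make_series(rnorm(100, 850, 60))
  pairing <- pair_beats(s, s, 0, align_config())
  rep1 <- compare_methods(pairing, level = "beat_by_beat")
  expect_equal(rep1$pearson$r, 1)
  expect_equal(rep1$icc$icc, 1)
  expect_equal(rep1$bland_altman$mean_diff, 0)

  # cohort with small per-beat noise: near-perfect subject-means agreement
  set.seed(74)
  pairings <- lapply(1:14, function(i) {
    ecg <- rnorm(250, runif(1, 682, 1017), 70)
    ecg <- pmin(pmax(ecg, 400), 2000)
    ppg <- ecg + rnorm(250, 0, 2)
    structure(list(lag = 0.25,
                   pairs = data.frame(ecg_beat_time_s = cumsum(ecg) / 1000,
                                      ecg_interval_ms = ecg,
                                      ppg_interval_ms = ppg)),
              class = "beat_pairing")
  })
  repm <- compare_methods(pairings, level = "subject_means",
                          metric = "mean_pi")
  expect_gt(repm$icc$icc, 0.99)
  expect_lt(abs(repm$bland_altman$mean_diff), 1)
  reps <- compare_methods(pairings, level = "subject_means", metric = "sdnn")
  expect_gt(reps$pearson$r, 0.9)
})

test_that("a linear distortion appears as proportional bias", {
  set.seed(75)
  ecg <- rnorm(400, 850, 90)
  ppg <- ecg + 0.01 * (ecg - mean(ecg)) + rnorm(400, 0, 2)
  ba <- bland_altman(ecg, ppg)   # ECG minus PPG
  expect_lt(abs(ba$prop_slope_b - (-0.01)), 2 * ba$prop_slope_se)
})
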
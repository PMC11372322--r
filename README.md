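# ppgbeats

Beat-by-beat pulse-interval extraction from smartphone-camera
photoplethysmography (PPG), with an ECG-referenced agreement battery.

## The problem

A fingertip pressed on a phone camera modulates the light reaching the
sensor with every heart beat: averaging each frame's pixel luminosity gives
a ~30 frames/s PPG signal whose systolic peaks mark pulse arrivals. The
time between successive peaks — the *pulse interval* — is the optical
analogue of the ECG R-R interval, and its standard deviation over an
artifact-free recording (SDNN) is a standard time-domain index of heart
rate variability (HRV). `ppgbeats` is for physiologists and digital-health
researchers who need a transparent, testable implementation of this
measurement chain and of the statistics used to validate it against ECG.

The package implements:

1. **PPG processing** — frame-luminosity averaging; zero-phase Butterworth
   bandpass (0.75–3 Hz); 5-frame unit-sum (Hann) smoothing; 180 Hz
   not-a-knot cubic-spline resampling; neighbour-comparison peak detection
   with topographic prominences; two validity filters (prominence > 30 % of
   the mean prominence of all maxima; prominence ≥ 75 % of the mean within
   a sliding 5-peak window, which removes dicrotic maxima).
2. **Interval cleaning** — pulse intervals in ms between valid peaks, then a
   multistep artifact rejection: per-200-interval quartile fences
   (`Q1 − 1.5·IQR`, `Q3 + 1.5·IQR`; the multiplier is configurable),
   a 20 % successive-difference implausibility rule against the last
   accepted beat, and exclusive 20–200 bpm physiological bounds.
3. **ECG reference** — a deterministic QRS-band R-wave detector, R-R
   intervals, and a flag-only ectopy screen.
4. **Beat alignment** — event-train cross-correlation for the PPG–ECG lag,
   then one-to-one nearest-neighbour beat pairing with an automated QC
   report in place of visual inspection.
5. **Agreement statistics** — per-recording HRV summaries (mean pulse
   interval, SDNN); Pearson correlation; single-rater two-way
   random-effects absolute-agreement intraclass correlation,

   ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1)·MS_E + (k/n)(MS_C − MS_E)),  k = 2,

   with its F-based 95 % CI; and Bland–Altman analysis (bias d̄, SD of
   differences, limits of agreement d̄ ± 1.96·SD, paired *t* test for fixed
   bias, OLS of difference on mean for proportional bias), with the
   ECG-minus-PPG difference direction throughout.
6. **A paired-recording simulator** — seeded synthetic ECG + camera-PPG
   recordings with known beat times, respiratory sinus arrhythmia, pulse
   transit delay, dicrotic waves, baseline drift, sensor noise and labelled
   beat artifacts, so every stage above is verifiable against ground truth.

## Worked example

Simulate a 5-minute recording with 2 % injected beat artifacts, run both
arms of the pipeline, and compare them beat by beat:

```r
library(ppgbeats)

cfg <- sim_config(seed = 42, duration_s = 300, artifact_fraction = 0.02)
rec <- simulate_recording(cfg)

peaks <- extract_ppg_peaks(rec$ppg, verbose = TRUE)
#> ppg peaks: detected 557 -> global 351 -> window 345
pi_ <- clean_intervals(compute_intervals(peaks), verbose = TRUE)
#> interval cleaning: quartile 5, successive 0, rate 0
hrv_summary(pi_)
#> <hrv_summary> n = 339, mean PI = 851.9 ms, SDNN = 73.1 ms

rpk <- detect_r_peaks(rec$ecg)
rr  <- clean_intervals(compute_rr_intervals(rpk))
lag <- estimate_lag(rpk, peaks)          # 0.25 s: the pulse transit delay
pairing <- pair_beats(rr, pi_, lag)
#> <beat_pairing> 337 pairs, lag 250 ms, unmatched ECG 4 / PPG 0

compare_methods(pairing, level = "beat_by_beat")
#> <agreement_report> beat_by_beat (interval_ms), n = 337
#>   Pearson r = 0.999 (p = 0)
#>   ICC(A,1) = 0.999 [0.998, 0.999]
#> <bland_altman> bias -0.18 (SD 3.90) ms, LoA [-7.8, 7.5], fixed-bias p = 0.407,
#>                slope b = 0.0155 (p = 6.03e-08, R2 = 0.08)
```

Reading the output: the raw resampled signal contains roughly two maxima
per beat (systolic + dicrotic); the prominence filters reduce them to one
per beat. Cleaning rejects the intervals disturbed by the injected
artifacts; the cross-correlation recovers the simulated 250 ms pulse
transit delay; and the paired intervals agree with the ECG reference to a
sub-millisecond mean bias with r and ICC ≈ 0.999.

## Command line

A thin wrapper over the same functions ships in `inst/cli/ppgbeats.R`:

```sh
Rscript inst/cli/ppgbeats.R simulate    --subjects 2 --seed 7 --out-dir sim
Rscript inst/cli/ppgbeats.R extract-ppg --ppg sim/subject_01/ppg.csv --out-dir out1
Rscript inst/cli/ppgbeats.R compare     --ecg sim/subject_01/ecg.csv \
                                        --ppg sim/subject_01/ppg.csv --out-dir cmp1
Rscript inst/cli/ppgbeats.R report      --in-dir cohort_cmp --out-dir cohort
```

Input CSVs use the headers `time_s,luminosity` (PPG, one row per frame) and
`time_s,voltage` (ECG). Every run writes a `manifest.json` (config
snapshot, input digests, per-stage counts, seed) from which it is exactly
reproducible. Exit codes: 0 success, 2 parse/argument error, 3 validation
error, 4 alignment failure.

## Documentation

The methods vignette (`vignettes/ppg-validation-methods.Rmd`) describes the
processing model, every tunable parameter with its default and rationale,
what the simulator does and does not emulate, and known limitations.
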
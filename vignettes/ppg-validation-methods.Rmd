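---
title: "Camera-PPG pulse intervals: processing model, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-PPG pulse intervals: processing model, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbeats)
```

## The measurement model

A fingertip over a phone camera yields one mean-luminosity value per video
frame at a nominal 30 frames/s. Pulsatile blood volume absorbs light, so
each systolic pulse is a luminosity *dip* riding on slow baseline drift
(ambient light, contact pressure) and sensor noise. The quantity of
interest is the sequence of pulse intervals — times between successive
systolic peaks, in ms — and its summary statistics: the mean pulse interval
and SDNN, the sample SD of the artifact-free ("normal-to-normal")
intervals. Against a simultaneously recorded ECG, validity is assessed
beat by beat and at the subject-summary level with Pearson correlation,
an absolute-agreement intraclass correlation, and Bland–Altman analysis.

## The PPG processing chain

`extract_ppg_peaks()` applies six stages. Their order matters: filtering
and smoothing operate on the native 30 Hz grid, and only then is the signal
refined to a 180 Hz grid, so the spline sharpens peak-time resolution
(5.6 ms quantisation) without resampling noise.

1. **Regularisation.** Frame timestamps may jitter; if the worst spacing
   deviates less than 20 % of the nominal period the series is treated as
   uniform at 30 Hz, otherwise it is an error — digital filters on a
   distorted grid silently corrupt timing, and we prefer failure to that.
   Luminosity is negated by default (`invert_luminosity`) so pulses point
   upward.
2. **Bandpass, 0.75–3 Hz.** A Butterworth filter of order 2, applied
   forward and backward (zero phase): phase distortion would displace peak
   times, the one thing this pipeline must preserve. The band covers pulse
   fundamentals from 45 to 180 bpm while rejecting drift and frame-rate
   noise. The effective order is therefore 4; the one-way order is
   configurable. Ends are padded by odd reflection over about three periods
   of the low corner, because the 0.75 Hz corner's start-up transient
   otherwise contaminates several seconds at each end. The mean is removed
   first; it carries no information in a bandpass and its transient would
   leak numerical residue into a nominally zero output.
3. **Smoothing.** Convolution with a 5-frame window scaled to unit sum.
   The default shape is a Hann window (effectively 3 active taps at length
   5); a flat moving average is selectable. Unit sum preserves constants,
   and the symmetric window preserves interior linear trends; reflection
   padding keeps output length equal to input length without amplitude
   collapse at the ends.
4. **Resampling, 180 Hz.** A cubic spline with not-a-knot end conditions,
   evaluated on `floor(duration × 180) + 1` points. Not-a-knot reproduces
   cubic polynomials exactly, which gives the implementation a sharp test
   surface (any boundary-handling bug breaks exact reproduction). The
   solver is a sparse moment system (`Matrix`), linear in record length.
5. **Peak detection.** Simple neighbour comparison: sample *i* is a peak
   iff `x[i-1] < x[i] >= x[i+1]`; a flat plateau yields its first sample.
   The rule is deliberately asymmetric so every plateau produces exactly
   one deterministic peak. Topographic prominence (height above the higher
   of the two lowest descents toward a strictly higher sample or the record
   edge) is computed for every peak.
6. **Validity filters.** First globally: keep peaks with prominence
   strictly above 30 % of the mean prominence of all detected maxima. Then
   locally: around each peak place a 5-peak window — clamped at the list
   ends so it keeps its full width whenever five peaks exist — and discard
   the peak if its prominence falls below 75 % of the window mean. The
   window pass runs once, against the pre-filter peak list; removals do not
   re-enter the means. The windowed rule is what removes dicrotic
   (diastolic) maxima, which are locally small but can exceed a global
   threshold in low-amplitude stretches.

Filtering a band this narrow reshapes the waveform: most harmonics above
3 Hz are discarded, so the filtered pulse is close to sinusoidal and every
raw beat typically contributes a second (rebound) maximum that the
prominence filters must remove — visible in the stage counts as roughly
two detected maxima per beat.

## Interval cleaning

`clean_intervals()` applies three rules in a fixed order, accumulating
per-interval status codes and never altering values:

* **Quartile fences per 200-interval segment.** Thresholds come from Q1 and
  Q3 of each segment (type-7 quantiles). The default fences are Tukey's
  `Q1 − 1.5·IQR` and `Q3 + 1.5·IQR`; `fence_multiplier = 0` gives the
  literal `[Q1, Q3]` band instead. The literal band removes ~50 % of all
  beats by construction, which cannot be the intent of an artifact filter,
  so the Tukey form — the standard robust-outlier construction in the
  artifact-detection literature — is the default; both behaviours are kept
  because the narrower reading is genuinely defensible from the wording
  that inspired it. The 200-interval window length mirrors the on-device
  signal-quality window of the emulated app.
* **Successive differences.** An interval differing by more than 20 % from
  the most recent *accepted* interval is implausible at rest and is
  rejected. Comparing to the accepted rather than the preceding raw
  interval stops one artifact from poisoning the comparisons that follow;
  the first valid interval seeds the reference.
* **Rate bounds.** Heart rates strictly below 20 bpm or strictly above
  200 bpm are rejected; 300 ms and 3000 ms survive (exclusive bounds).

Rejected beats are removed from analysis, never interpolated or imputed.

## ECG reference and alignment

The R-wave detector is intentionally minimal and fully deterministic:
zero-phase Butterworth bandpass onto the QRS energy band (5–25 Hz), local
maxima, a two-step prominence gate (first 25 % of the maximum prominence to
exclude the noise floor, then 50 % of the median candidate prominence), and
a 250 ms refractory rule keeping the larger of any offending pair. All
thresholds are relative, making the detector exactly invariant to gain and
offset. A single median-of-all-maxima threshold is *not* noise robust —
broadband noise creates thousands of tiny maxima that drag the median to
the noise floor — hence the candidate gate. The detector is adequate for
clean laboratory ECG and is oracle-testable; it is not an arrhythmia-grade
algorithm, and the surrounding code treats it as pluggable. Ectopy
screening (`screen_ectopy()`) only *flags* intervals deviating more than
30 % from an 11-point running median, for human review.

Alignment estimates the PPG-minus-ECG lag (clock offset plus pulse transit
delay) by cross-correlating the two event trains binned at 10 ms and
smoothed with a 50 ms Gaussian kernel, searching ±2 s with ties resolved
toward zero lag. Pairing is nearest-neighbour, one-to-one, closest-wins
within 500 ms. An interval pair requires both its start and end beats to be
matched to each other: without the start-beat condition, a merged interval
(missed beat) would pair against a single reference interval and
contaminate the agreement statistics. The QC report replaces the visual
alignment check with a pairing fraction (matched beats over the larger
train; < 0.9 flags the recording) and the median absolute residual.

## Agreement statistics

ICC(A,1) — two-way random effects, absolute agreement, single rater — is
computed from explicit sums of squares with the standard F-based 95 % CI
(Satterthwaite degrees of freedom); the test suite checks it against an
independent `aov`-based computation to 1e-10. Absolute agreement penalises
systematic offsets: a constant shift leaves Pearson's r at 1 while the ICC
collapses, which is exactly why both are reported. When there is no
between-subject variance the ICC is undefined; we report 0 with a warning
flag rather than NaN, since "no agreement demonstrable" is the
conservative reading. Bland–Altman uses the sample SD and a 1.96
multiplier for the limits of agreement, the paired two-tailed *t* test for
fixed bias, and OLS of difference on mean for proportional bias, with
ECG-minus-PPG differences everywhere. SDNN uses the n−1 denominator, the
convention in the HRV literature. Printed reports round ms quantities to
one decimal and correlations to two, but full precision is always retained
in the objects.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe a 5-minute seated resting recording:
mean RR 857 ms, SDNN ≈ 73 ms, breathing at 0.25 Hz, transit delay 250 ms,
dicrotic waves at 40 % relative amplitude and 35 % of the local RR after
the systolic peak, baseline drift at 0.05 Hz, and white sensor noise.
Design choices worth stating explicitly:

* **Variance decomposition.** SDNN² = A²/2 + σ² with RSA amplitude
  A = 102 ms and white beat noise σ = 10 ms. Resting young adults are
  vagally dominated: the beat-to-beat (RMSSD-like) component is small, and
  an artifact-free recording must itself satisfy the 20 %
  successive-difference rule — a generator whose *clean* beats routinely
  violated the physiological-implausibility criterion would contradict the
  premise of the filters it is meant to exercise. With these defaults the
  largest clean beat-to-beat change is ≈ 128 ms, below the ≈ 171 ms
  threshold at this mean RR.
* **Pulse morphology.** The systolic pulse is a two-half-Gaussian bump
  (rise σ 75 ms, decay σ 85 ms). The mild asymmetry is a deliberate
  calibration: a zero-phase 0.75–3 Hz bandpass shifts the maximum of an
  asymmetric bump toward its centre of mass, and a strongly skewed
  waveform (e.g. 55/110 ms) displaces the filtered peak by ~30 ms, which
  would make the generator's own peak-time ground truth meaningless for
  timing checks. With the default shape the end-to-end displacement stays
  under one 180 Hz sample. This is a property the generator must have for
  ground-truth timing to be interpretable, not a claim about real pulse
  shapes, which are more asymmetric.
* **Edge margins.** The first beat sits at 0.5 s and the last at least
  ~1.2 s before the record end, so every ECG complex and transit-delayed
  PPG pulse lies wholly inside the record and "true beat count" is exact.
* **Artifacts.** `inject_artifacts()` disturbs a seeded selection of
  intervals with missed beats (merge), double detections (0.45/0.55 split)
  or spikes (×0.4 / ×2.5), relabelling every affected interval. Beat times
  are rebuilt as cumulative sums, so the ground-truth consistency invariant
  survives injection.
* **Cohort.** `simulate_cohort()` draws per-subject mean RR uniformly from
  682–1017 ms (≈ 59–88 bpm) and SDNN targets from N(73, 23²) ms truncated
  to [25, 130] ms, realising each target through the RSA amplitude.

Not emulated: real pulse-waveform morphology (and its dependence on
vascular tone), skin-tone and perfusion optics, time-varying transit
delay, frame drops, motion transients that corrupt the luminosity itself
rather than beat timing, and any arrhythmia. Passing the end-to-end suites
therefore demonstrates that the *implementation* is faithful and that the
method behaves as designed under its stated assumptions — it is not
clinical validation on real recordings.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation), configurable.
* A perfectly flat recording yields an empty peak set: maxima whose
  prominence is below 1e-9 of the input amplitude are treated as arithmetic
  residue of the filters, not pulses.
* Ties in the lag search resolve to the smallest |lag|; ties in beat
  matching resolve closest-first.
* Zero-variance inputs: Pearson refuses (undefined); Bland–Altman on
  identical inputs reports exact zeros rather than NaN slopes; degenerate
  ICC reports 0 with a flag.
* Problem sizes in the shipped test-and-acceptance runs (20 simulated
  subjects of 300 s for recovery and artifact suites, 50 random instances
  per brute-force oracle, a 14-subject cohort for the subject-means
  battery) were chosen to estimate each property stably while keeping a
  full run in the minutes range on one core.

## Known limitations

* The pipeline assumes a cooperative resting recording; it removes
  artifacts but makes no attempt to recover beats inside long corrupted
  stretches.
* The quartile filter's literal-vs-fenced ambiguity is resolved by
  configuration, not by evidence about the original implementation.
* The R detector's refractory rule caps detectable rates at 240 bpm.
* Subject-means ICCs on small cohorts carry wide F-based CIs; the
  beat-by-beat level is where this design has statistical power.
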
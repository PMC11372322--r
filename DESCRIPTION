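Package: ppgbeats
Title: Pulse-Interval Extraction and ECG Agreement Analysis for Camera-Based Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts beat-by-beat pulse intervals from smartphone-camera
    photoplethysmography (PPG) recordings stored as frame-luminosity time
    series, using a zero-phase Butterworth bandpass, windowed smoothing, cubic
    spline resampling, neighbour-comparison peak detection and two
    prominence-based validity filters, followed by a multistep pulse-interval
    artifact rejection procedure (windowed quartile fences, successive-difference
    screening, physiological rate bounds).  Provides matching ECG R-wave
    detection, cross-correlation beat alignment, time-domain heart rate
    variability summaries (SDNN), and a method-comparison battery (Pearson
    correlation, two-way random-effects absolute-agreement intraclass
    correlation, Bland-Altman limits of agreement with fixed and proportional
    bias tests).  Includes a seeded simulator of paired ECG/PPG recordings with
    known beat times, respiratory sinus arrhythmia, dicrotic waves, baseline
    drift and labelled artifacts, so every stage is verifiable against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    Matrix,
    jsonlite,
    optparse,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
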
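#' Configuration of ECG/PPG beat alignment
#'
#' @param max_lag_s Half-width of the lag search range in seconds
#'   (default 2; pulse transit delays are of order 0.1--0.3 s).
#' @param lag_grid_ms Lag search grid in ms (default 10, much finer than a
#'   beat).
#' @param match_tolerance_ms Maximum |time difference| for a PPG beat to be
#'   matched to an ECG beat after lag correction (default 500 ms).
#' @param smooth_kernel_ms Standard deviation of the Gaussian kernel applied
#'   to the binned event trains before cross-correlation (default 50 ms).
#' @return A list of class `align_config`.
#' @export
align_config <- function(max_lag_s = 2.0, lag_grid_ms = 10,
                         match_tolerance_ms = 500, smooth_kernel_ms = 50) {
  if (max_lag_s <= 0 || lag_grid_ms <= 0 || match_tolerance_ms <= 0 ||
      smooth_kernel_ms <= 0)
    stop("all alignment parameters must be positive", call. = FALSE)
  structure(list(max_lag_s = max_lag_s, lag_grid_ms = lag_grid_ms,
                 match_tolerance_ms = match_tolerance_ms,
                 smooth_kernel_ms = smooth_kernel_ms),
            class = "align_config")
}

#' Estimate the PPG-minus-ECG lag by event-train cross-correlation
#'
#' Bins both peak trains into impulse series on a `lag_grid_ms` grid, smooths
#' each with a Gaussian kernel, and returns the lag in `[-max_lag_s,
#' max_lag_s]` that maximises their cross-correlation; ties resolve to the
#' smallest |lag|.  A positive lag means PPG events occur *after* the
#' corresponding ECG events (clock offset plus pulse transit delay).
#'
#' @param ecg_peaks,ppg_peaks [peak_set()]s with >= 10 peaks each.
#' @param cfg An [align_config()].
#' @return The estimated lag in seconds.
#' @export
estimate_lag <- function(ecg_peaks, ppg_peaks, cfg = align_config()) {
  stopifnot(inherits(ecg_peaks, "peak_set"), inherits(ppg_peaks, "peak_set"))
  te <- ecg_peaks$peak_times
  tp <- ppg_peaks$peak_times
  if (length(te) < 10L || length(tp) < 10L)
    stop("lag estimation needs at least 10 peaks in each train", call. = FALSE)
  if (min(tp) - cfg$max_lag_s > max(te) || max(tp) + cfg$max_lag_s < min(te))
    stop("recordings do not overlap within the lag search range",
         call. = FALSE)
  dt <- cfg$lag_grid_ms / 1000
  t0 <- min(te, tp) - cfg$max_lag_s
  t1 <- max(te, tp) + cfg$max_lag_s
  nb <- ceiling((t1 - t0) / dt) + 1L
  bin <- function(tt) tabulate(pmin(nb, floor((tt - t0) / dt) + 1L), nb)
  sd_bins <- cfg$smooth_kernel_ms / cfg$lag_grid_ms
  half <- ceiling(3 * sd_bins)
  kern <- stats::dnorm(-half:half, sd = sd_bins)
  sm <- function(v) as.numeric(stats::filter(c(rep(0, half), v, rep(0, half)),
                                             kern, sides = 2)[(half + 1L):(half + nb)])
  e <- sm(bin(te))
  p <- sm(bin(tp))
  max_k <- floor(cfg$max_lag_s / dt)
  lags <- -max_k:max_k
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(e[1:(nb - k)] * p[(1 + k):nb])
    else        sum(e[(1 - k):nb] * p[1:(nb + k)])
  }, numeric(1))
  best <- which(cc == max(cc))
  lags[best[which.min(abs(lags[best]))]] * dt
}

# Greedy one-to-one nearest matching of two event-time vectors; returns an
# integer vector m with m[i] = index in b matched to a[i] (NA if unmatched).
match_events <- function(a, b, tol) {
  m <- rep(NA_integer_, length(a))
  used <- logical(length(b))
  cand <- do.call(rbind, lapply(seq_along(a), function(i) {
    j <- which(abs(b - a[i]) <= tol)
    if (length(j)) cbind(i = i, j = j, d = abs(b[j] - a[i])) else NULL
  }))
  if (is.null(cand)) return(m)
  cand <- cand[order(cand[, "d"]), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, "i"]; j <- cand[r, "j"]
    if (is.na(m[i]) && !used[j]) {
      m[i] <- j
      used[j] <- TRUE
    }
  }
  m
}

# Peak times implied by an interval series: the start of the first interval
# plus every interval-ending beat.
series_peak_times <- function(series) {
  c(series$beat_times[1] - series$intervals[1] / 1000, series$beat_times)
}

#' Pair ECG and PPG beats one-to-one for beat-by-beat comparison
#'
#' Shifts the PPG beat times by `-lag`, then matches beats to the nearest ECG
#' beat within `match_tolerance_ms`, one-to-one with closest-wins ties.  An
#' interval pair is formed only when both its ending beats *and* its starting
#' beats are matched to each other and both intervals are valid — so a missed
#' or rejected beat on either side drops the affected intervals instead of
#' pairing a merged interval against a single one.
#'
#' @param ecg,ppg [interval_series()] objects (>= 2 valid intervals each).
#' @param lag PPG-minus-ECG lag in seconds, from [estimate_lag()].
#' @param cfg An [align_config()].
#' @return An object of class `beat_pairing`: list with `lag`, `pairs` (data
#'   frame `ecg_beat_time_s`, `ecg_interval_ms`, `ppg_interval_ms`,
#'   `residual_s`), `n_unmatched_ecg`, `n_unmatched_ppg`.
#' @export
pair_beats <- function(ecg, ppg, lag, cfg = align_config()) {
  stopifnot(inherits(ecg, "interval_series"), inherits(ppg, "interval_series"))
  if (sum(ecg$status == "valid") < 2L || sum(ppg$status == "valid") < 2L)
    stop("need at least 2 valid intervals on each side", call. = FALSE)
  te <- series_peak_times(ecg)
  tp <- series_peak_times(ppg) - lag
  m <- match_events(te, tp, cfg$match_tolerance_ms / 1000)
  ne <- length(ecg$intervals)
  rows <- lapply(seq_len(ne), function(i) {
    # interval i runs from beat i to beat i+1 (in peak-time indexing)
    j0 <- m[i]; j1 <- m[i + 1L]
    if (is.na(j0) || is.na(j1) || j1 != j0 + 1L) return(NULL)
    if (ecg$status[i] != "valid" || ppg$status[j0] != "valid") return(NULL)
    data.frame(ecg_beat_time_s = ecg$beat_times[i],
               ecg_interval_ms = ecg$intervals[i],
               ppg_interval_ms = ppg$intervals[j0],
               residual_s = tp[j1] - te[i + 1L])
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("no beat pairs found; alignment failed", call. = FALSE)
  structure(list(lag = lag, pairs = pairs,
                 n_matched_beats = sum(!is.na(m)),
                 n_ecg_beats = length(te), n_ppg_beats = length(tp),
                 n_unmatched_ecg = sum(is.na(m)),
                 n_unmatched_ppg = length(tp) - sum(!is.na(m))),
            class = "beat_pairing")
}

#' @export
print.beat_pairing <- function(x, ...) {
  cat(sprintf("<beat_pairing> %d pairs, lag %.0f ms, unmatched ECG %d / PPG %d\n",
              nrow(x$pairs), 1000 * x$lag, x$n_unmatched_ecg, x$n_unmatched_ppg))
  invisible(x)
}

#' Automated alignment quality-control summary
#'
#' Replaces per-recording visual inspection with a deterministic report: the
#' fraction of beats matched (relative to the larger beat train), the
#' estimated lag, and the median absolute beat-time residual after lag
#' correction.  Recordings with a pairing fraction below `min_fraction` are
#' flagged for review.
#'
#' @param pairing A [pair_beats()] result.
#' @param min_fraction Pairing fraction below which the recording is flagged
#'   (default 0.9).
#' @return A list: `pairing_fraction`, `lag_s`, `median_abs_residual_ms`,
#'   `n_pairs`, `flagged`.
#' @export
alignment_qc_report <- function(pairing, min_fraction = 0.9) {
  stopifnot(inherits(pairing, "beat_pairing"))
  frac <- pairing$n_matched_beats / max(pairing$n_ecg_beats,
                                        pairing$n_ppg_beats)
  list(pairing_fraction = frac,
       lag_s = pairing$lag,
       median_abs_residual_ms = 1000 * stats::median(abs(pairing$pairs$residual_s)),
       n_pairs = nrow(pairing$pairs),
       flagged = frac < min_fraction)
}
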
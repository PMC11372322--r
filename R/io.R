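read_two_column_csv <- function(path, col1, col2, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(col1, col2)) {
    if (!col %in% names(df))
      stop(sprintf("%s CSV %s is missing required column '%s'",
                   what, path, col), call. = FALSE)
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("%s CSV %s: non-numeric or missing value in column '%s' at data row %d",
                   what, path, col, bad[1]), call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Read a raw PPG recording from CSV
#'
#' Expects a header `time_s,luminosity` with one row per camera frame.
#'
#' @param path CSV file path.
#' @param nominal_rate Nominal frame rate, frames/s (default 30).
#' @return A [frame_series()].
#' @export
read_ppg_csv <- function(path, nominal_rate = 30) {
  df <- read_two_column_csv(path, "time_s", "luminosity", "PPG")
  frame_series(df$time_s, df$luminosity, nominal_rate = nominal_rate)
}

#' Read an ECG recording from CSV
#'
#' Expects a header `time_s,voltage` with uniformly sampled rows; the rate is
#' inferred from the median spacing unless given.
#'
#' @param path CSV file path.
#' @param rate Sampling rate in Hz; inferred when `NULL`.
#' @return A [uniform_signal()].
#' @export
read_ecg_csv <- function(path, rate = NULL) {
  df <- read_two_column_csv(path, "time_s", "voltage", "ECG")
  if (is.null(rate)) rate <- 1 / stats::median(diff(df$time_s))
  uniform_signal(df$voltage, rate = rate, start_time = df$time_s[1])
}

#' Write a frame series or uniform signal as CSV
#'
#' @param x A [frame_series()] or [uniform_signal()].
#' @param path Output CSV path; columns `time_s,value` (or
#'   `time_s,luminosity` / `time_s,voltage` when `value_name` is set).
#' @param value_name Column name for the values (default `"value"`).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, value_name = "value") {
  if (inherits(x, "frame_series")) {
    df <- data.frame(time_s = x$times, value = x$values)
  } else if (inherits(x, "uniform_signal")) {
    df <- data.frame(time_s = signal_times(x), value = x$values)
  } else stop("unsupported signal type", call. = FALSE)
  names(df)[2] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an interval series as CSV
#'
#' Columns: `beat_time_s,interval_ms,status`.
#'
#' @param series An [interval_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intervals_csv <- function(series, path) {
  stopifnot(inherits(series, "interval_series"))
  utils::write.csv(data.frame(beat_time_s = series$beat_times,
                              interval_ms = series$intervals,
                              status = series$status),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an interval series from CSV
#'
#' @param path CSV with columns `beat_time_s,interval_ms,status` (status
#'   optional; defaults to all valid).
#' @return An [interval_series()].
#' @export
read_intervals_csv <- function(path) {
  df <- read_two_column_csv(path, "beat_time_s", "interval_ms", "interval")
  status <- if ("status" %in% names(df)) df$status
            else rep("valid", nrow(df))
  interval_series(df$beat_time_s, df$interval_ms, status)
}

#' Write a run manifest as JSON
#'
#' Records everything needed to reproduce a run: the package version, the
#' seed, every configuration value, MD5 digests of the input files and the
#' per-stage counts.
#'
#' @param path Output JSON path.
#' @param configs Named list of configuration objects.
#' @param inputs Character vector of input file paths (digested).
#' @param counts Named list/vector of per-stage counts.
#' @param seed Seed used, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, configs = list(), inputs = character(0),
                           counts = list(), seed = NULL) {
  digests <- if (length(inputs))
    stats::setNames(as.list(tools::md5sum(inputs)), basename(inputs))
  else list()
  manifest <- list(
    package = "ppgbeats",
    version = as.character(utils::packageVersion("ppgbeats")),
    seed = seed,
    configs = lapply(configs, function(cf) lapply(unclass(cf), unclass)),
    input_digests = digests,
    stage_counts = as.list(counts))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
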
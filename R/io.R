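#' Construct a signal channel
#'
#' A uniformly sampled raw sensor trace: amplitude samples plus a sampling
#' rate and a start time. No per-sample timestamps are stored.
#'
#' @param label Channel name; one of `red`, `ir`, `acc_x`, `acc_y`, `acc_z`.
#' @param samples Numeric vector of amplitudes (arbitrary sensor units).
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `signal_channel`.
#' @export
signal_channel <- function(label, samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  structure(list(label = label, fs = fs, t0 = t0,
                 samples = as.numeric(samples)),
            class = "signal_channel")
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf("<signal_channel '%s'> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Duration of a signal channel in seconds
#' @param channel A [signal_channel()].
#' @return Duration in seconds.
#' @export
channel_duration <- function(channel) length(channel$samples) / channel$fs

#' Read a multichannel recording from a delimited file
#'
#' Reads a CSV with a header row naming a `time` column (seconds) and one
#' column per sensor channel. The sampling rate of each channel is inferred
#' from the median time delta unless supplied explicitly. All returned
#' channels share the recording's start time.
#'
#' @param path CSV file path.
#' @param expected_channels Character vector of channel names that must be
#'   present; an informative error is raised for any missing one.
#' @param fs Optional named numeric vector/list of per-channel sampling rates
#'   in Hz (e.g. from a sidecar config), overriding inference.
#' @return Named list of [signal_channel()] objects, one per requested
#'   channel.
#' @export
read_recording <- function(path, expected_channels, fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop("recording file must contain a 'time' column")
  tt <- df$time
  if (any(diff(tt) <= 0))
    stop("time column must be strictly increasing")
  missing <- setdiff(expected_channels, names(df))
  if (length(missing))
    stop(sprintf("channel %s not found in %s",
                 paste(missing, collapse = ", "), path))
  fs_inferred <- 1 / stats::median(diff(tt))
  out <- lapply(expected_channels, function(ch) {
    ch_fs <- if (!is.null(fs) && ch %in% names(fs)) as.numeric(fs[[ch]])
             else fs_inferred
    x <- df[[ch]]
    keep <- !is.na(x)
    signal_channel(ch, x[keep], ch_fs, t0 = tt[1])
  })
  names(out) <- expected_channels
  out
}

#' Write a multichannel recording to a delimited file
#'
#' Inverse of [read_recording()] for channels sharing one sampling rate:
#' writes a `time` column plus one column per channel. Channels with
#' different rates must be written to separate files.
#'
#' @param channels Named list of [signal_channel()] objects with equal `fs`
#'   and `t0`.
#' @param path Output CSV path.
#' @export
write_recording <- function(channels, path) {
  fs <- unique(vapply(channels, function(c) c$fs, numeric(1)))
  if (length(fs) != 1)
    stop("all channels in one file must share a sampling rate")
  n <- unique(vapply(channels, function(c) length(c$samples), integer(1)))
  if (length(n) != 1) stop("all channels must have equal length")
  t0 <- channels[[1]]$t0
  df <- data.frame(time = t0 + (seq_len(n) - 1) / fs)
  for (ch in channels) df[[ch$label]] <- ch$samples
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Sliding analysis windows over a channel
#'
#' Emits overlapping windows of `spec$length_s` seconds hopping by
#' `spec$step_s` seconds. Windows are timestamped at their END: the window
#' reported at time `t` covers the preceding `length_s` seconds, so the
#' estimator is causal. The first window ends at `t = length_s` and the count
#' is `floor((duration - length_s)/step_s) + 1`.
#'
#' @param channel A [signal_channel()].
#' @param spec A [window_spec()].
#' @return A list with elements `t` (numeric vector of window end times,
#'   relative to `t0`) and `windows` (list of numeric sample vectors, each of
#'   exactly `length_s * fs` samples). Empty (with a warning) if the channel
#'   is shorter than one window.
#' @export
sliding_windows <- function(channel, spec = window_spec()) {
  fs <- channel$fs
  dur <- channel_duration(channel)
  if (dur < spec$length_s) {
    warning(sprintf("recording (%.1f s) shorter than one %g s window",
                    dur, spec$length_s))
    return(list(t = numeric(0), windows = list()))
  }
  nwin <- floor((dur - spec$length_s) / spec$step_s) + 1
  tend <- spec$length_s + (seq_len(nwin) - 1) * spec$step_s
  len <- round(spec$length_s * fs)
  windows <- lapply(tend, function(t) {
    i1 <- round((t - spec$length_s) * fs) + 1
    channel$samples[i1:(i1 + len - 1)]
  })
  list(t = tend, windows = windows)
}

#' Write rate estimates to a delimited file
#'
#' One row per processed timestep with columns `t`, `rate_value` (empty when
#' no point value was emitted), `band_low`, `band_high`, `confident` (0/1).
#' Lossless round-trip with [read_estimates()].
#'
#' @param estimates Data frame as produced by [estimate_rates()] (columns
#'   `t`, `rate_value`, `band_low`, `band_high`, `confident`).
#' @param path Output CSV path.
#' @export
write_estimates <- function(estimates, path) {
  df <- estimates[, c("t", "rate_value", "band_low", "band_high",
                      "confident")]
  df$confident <- as.integer(df$confident)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read rate estimates written by [write_estimates()]
#' @param path CSV path.
#' @return Data frame with columns `t`, `rate_value`, `band_low`,
#'   `band_high`, `confident` (logical).
#' @export
read_estimates <- function(path) {
  df <- utils::read.csv(path)
  df$confident <- as.logical(df$confident)
  df
}

#' Read a reference rate series
#'
#' @param path CSV with columns `time` (seconds) and `rate` (per-minute).
#' @param units `"BPM"` or `"BrPM"` (annotation only).
#' @return A data frame of class `rate_series` with columns `time`, `rate`.
#' @export
read_rate_series <- function(path, units = c("BPM", "BrPM")) {
  units <- match.arg(units)
  df <- utils::read.csv(path)
  stopifnot(all(c("time", "rate") %in% names(df)))
  if (any(diff(df$time) <= 0)) stop("reference times must be increasing")
  if (any(df$rate < 0)) stop("reference rates must be non-negative")
  attr(df, "units") <- units
  class(df) <- c("rate_series", class(df))
  df
}
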
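#' Standardize a numeric sequence
#'
#' Subtracts the mean and divides by the (population-agnostic, `stats::sd`)
#' standard deviation. A constant input returns all zeros rather than NaN so
#' degenerate windows propagate harmlessly.
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector with mean ~0 and sd ~1 (or all zeros).
#' @export
standardize <- function(x) {
  stopifnot(length(x) > 0)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Reflect-padded running median; k odd. Removes transient spikes shorter
# than k/2 samples without smearing edges.
median_despike <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1
  if (k <= 1 || length(x) <= k) return(x)
  h <- (k - 1) / 2
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(length(x) - h):(length(x) - 1)]))
  y <- stats::runmed(xp, k)
  y[(h + 1):(h + length(x))]
}

# Cache of central Savitzky-Golay smoothing kernels keyed by "p:n".
.sg_cache <- new.env(parent = emptyenv())

sg_kernel <- function(p, n) {
  key <- paste(p, n, sep = ":")
  if (!is.null(.sg_cache[[key]])) return(.sg_cache[[key]])
  F <- signal::sgolay(p, n)
  k <- as.numeric(F[(n + 1) / 2, ])
  .sg_cache[[key]] <- k
  k
}

# FFT linear convolution of x with kernel k (odd length), reflect padding.
conv_same <- function(x, k) {
  h <- (length(k) - 1) / 2
  nx <- length(x)
  left <- rev(x[2:(h + 1)])
  right <- rev(x[(nx - h):(nx - 1)])
  xp <- c(left, x, right)
  m <- length(xp) + length(k) - 1
  nfft <- stats::nextn(m)
  X <- stats::fft(c(xp, numeric(nfft - length(xp))))
  K <- stats::fft(c(k, numeric(nfft - length(k))))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  full[(2 * h + 1):(2 * h + nx)]
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with an odd window. The window length
#' is given in seconds and converted to the nearest odd sample count at the
#' channel's sampling rate. Edges are handled by reflect padding.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds.
#' @param p Polynomial order (default 2).
#' @return Smoothed vector, same length as `x`.
#' @export
sg_smooth <- function(x, fs, window_s, p = 2) {
  n <- round(window_s * fs)
  if (n %% 2 == 0) n <- n + 1
  if (n < p + 2) n <- p + 3 - (p %% 2)  # minimal odd window
  if (n >= length(x)) stop("Savitzky-Golay window longer than the signal")
  conv_same(x, sg_kernel(p, n))
}

butter_bandpass <- function(low, high, fs, order = 1) {
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

# Zero-phase band-pass. Filters are run forward-backward so spectral peaks
# are not displaced by group delay.
bandpass_zero_phase <- function(x, fs, low, high, order = 1) {
  as.numeric(signal::filtfilt(butter_bandpass(low, high, fs, order), x))
}

#' Pulse preprocessing of one 30-s PPG window
#'
#' Implements the pulse pipeline: each channel is anti-alias decimated from
#' 400 Hz to 100 Hz, despiked with a 0.05 s median filter, band-passed with a
#' 1st-order \[0.5, 4\] Hz Butterworth (zero-phase) and standardized; the two
#' standardized channels are summed sample-wise; a 2nd-order Savitzky-Golay
#' baseline (1.6 s window) is subtracted from the sum; the result is
#' standardized.
#'
#' @param red,ir Raw Red / IR window samples (equal length, 400 Hz, 30 s).
#' @param fs_in Input sampling rate in Hz (default 400).
#' @param fs_out Working rate after decimation (default 100).
#' @param t Window end time in seconds (metadata only).
#' @return A `processed_segment`: list with `t`, `task = "pulse"`,
#'   `modality = "ppg"`, `fs` (= `fs_out`) and standardized `samples`.
#' @export
preprocess_pulse_window <- function(red, ir, fs_in = 400, fs_out = 100,
                                    t = NA_real_) {
  if (length(red) != length(ir))
    stop("red and ir windows must have equal length")
  q <- fs_in / fs_out
  one <- function(x) {
    if (all(x == x[1])) return(rep(0, ceiling(length(x) / q)))
    x <- x - mean(x)   # keeps IIR edge transients independent of DC offset
    if (q > 1) x <- as.numeric(signal::decimate(x, q, ftype = "iir"))
    x <- median_despike(x, round(0.05 * fs_out))
    x <- bandpass_zero_phase(x, fs_out, 0.5, 4)
    standardize(x)
  }
  combined <- one(red) + one(ir)
  if (all(combined == 0)) {
    out <- combined
  } else {
    baseline <- sg_smooth(combined, fs_out, 1.6, p = 2)
    out <- standardize(combined - baseline)
  }
  structure(list(t = t, task = "pulse", modality = "ppg", fs = fs_out,
                 samples = out),
            class = "processed_segment")
}

#' Stream-level respiratory band-pass
#'
#' The respiratory pipeline band-passes each full-length channel stream
#' (1st-order \[0.1, 1\] Hz Butterworth, zero-phase) before the sliding
#' window cuts segments, so slow components are handled without window-edge
#' transients.
#'
#' @param channel A [signal_channel()].
#' @return The channel with filtered samples.
#' @export
resp_prefilter <- function(channel) {
  x <- channel$samples - mean(channel$samples)  # offset-free edge transients
  channel$samples <- bandpass_zero_phase(x, channel$fs, 0.1, 1)
  channel
}

#' Respiratory preprocessing of one window
#'
#' Per-window stage of the respiratory pipeline, applied to windows cut from
#' [resp_prefilter()]ed streams (PPG Red/IR or accelerometer Y/Z): each
#' channel is smoothed with a 2nd-order, 2 s Savitzky-Golay filter and
#' standardized; the channels are summed; the sum is smoothed again (same
#' filter), differentiated (first difference scaled by `fs`, first value
#' repeated to preserve length) to suppress residual baseline, and
#' standardized.
#'
#' @param ch_a,ch_b Band-passed window samples (equal length).
#' @param fs Sampling rate in Hz.
#' @param modality `"ppg"` or `"acc"` (metadata).
#' @param t Window end time in seconds (metadata).
#' @return A `processed_segment` with `task = "respiratory"`.
#' @export
preprocess_resp_window <- function(ch_a, ch_b, fs, modality = "ppg",
                                   t = NA_real_) {
  if (length(ch_a) != length(ch_b))
    stop("channel windows must have equal length")
  one <- function(x) {
    if (all(x == x[1])) return(rep(0, length(x)))
    standardize(sg_smooth(x, fs, 2, p = 2))
  }
  combined <- one(ch_a) + one(ch_b)
  if (all(combined == 0)) {
    out <- combined
  } else {
    sm <- sg_smooth(combined, fs, 2, p = 2)
    d <- diff(sm) * fs
    d <- c(d[1], d)
    out <- standardize(d)
  }
  structure(list(t = t, task = "respiratory", modality = modality, fs = fs,
                 samples = out),
            class = "processed_segment")
}

#' @export
print.processed_segment <- function(x, ...) {
  cat(sprintf("<processed_segment> %s/%s, %d samples @ %g Hz, t = %s s\n",
              x$task, x$modality, length(x$samples), x$fs,
              format(x$t)))
  invisible(x)
}
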
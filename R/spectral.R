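#' Zero-padded amplitude spectrum
#'
#' Magnitude of the real-input DFT after zero-padding to `pad_to` samples.
#' Frequencies are `k * fs / pad_to` for bins `k = 0 .. floor(pad_to/2)`.
#'
#' @param x Non-empty numeric vector.
#' @param fs Sampling rate in Hz.
#' @param pad_to Total length after zero padding; must be >= `length(x)`.
#' @return List with `freqs` (Hz) and `magnitudes`.
#' @export
amplitude_spectrum <- function(x, fs, pad_to = length(x)) {
  stopifnot(length(x) > 0, pad_to >= length(x))
  X <- stats::fft(c(x, numeric(pad_to - length(x))))
  nkeep <- floor(pad_to / 2) + 1
  list(freqs = (seq_len(nkeep) - 1) * fs / pad_to,
       magnitudes = Mod(X[seq_len(nkeep)]))
}

softmax <- function(z) {
  z <- z - max(z)              # numerical stability; softmax is shift-invariant
  e <- exp(z)
  e / sum(e)
}

#' Per-rate probability estimate of a segment
#'
#' Converts a (sub-)segment into a probability over integer per-minute rates:
#' the DFT is zero-padded to `60 * fs` samples so the bin spacing is exactly
#' one per-minute unit and every integer rate in the task's range maps to one
#' bin; the in-range magnitudes are standardized and passed through a softmax,
#' pulling dominant components apart while guaranteeing the probabilities sum
#' to 1. A degenerate (all-zero) segment yields the uniform distribution.
#'
#' @param x Segment samples (standardized upstream; at least
#'   `cfg$min_subseg_s * fs` samples).
#' @param fs Sampling rate in Hz.
#' @param cfg A [task_config()].
#' @return Object of class `rate_probability`: list with integer `rates` and
#'   `probs` summing to 1.
#' @export
get_proba_estimations <- function(x, fs, cfg) {
  if (length(x) < cfg$min_subseg_s * fs)
    stop(sprintf("segment too short for probability estimation (%d < %g)",
                 length(x), cfg$min_subseg_s * fs))
  pad_to <- 60 * fs
  if (pad_to < length(x)) pad_to <- length(x)  # guard; never hit at 30 s windows
  spec <- amplitude_spectrum(x, fs, pad_to)
  rates <- cfg$rate_range
  # bin k has frequency k*fs/(60*fs) = k/60 Hz = k per-minute units
  mags <- spec$magnitudes[rates + 1L]
  z <- standardize(mags)
  structure(list(rates = rates, probs = softmax(z)),
            class = "rate_probability")
}

#' @export
print.rate_probability <- function(x, ...) {
  top <- order(x$probs, decreasing = TRUE)[1:3]
  cat(sprintf("<rate_probability> %d rates; top: %s\n", length(x$rates),
              paste(sprintf("%d (%.3f)", x$rates[top], x$probs[top]),
                    collapse = ", ")))
  invisible(x)
}
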
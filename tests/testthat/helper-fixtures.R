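# Shared fixtures built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pure tone as a standardized 30 s segment.
tone_segment <- function(rate_per_min, fs = 100, dur = 30, phase = 0) {
  t <- (seq_len(dur * fs) - 1) / fs
  standardize(sin(2 * pi * rate_per_min / 60 * t + phase))
}

# Direct O(n^2) DFT magnitude: independent oracle for amplitude_spectrum.
dft_magnitude_oracle <- function(x, pad_to = length(x)) {
  x <- c(x, numeric(pad_to - length(x)))
  n <- length(x)
  k <- 0:(floor(n / 2))
  vapply(k, function(kk) {
    w <- -2 * pi * kk * (0:(n - 1)) / n
    Mod(sum(x * complex(real = cos(w), imaginary = sin(w))))
  }, numeric(1))
}

# Independent softmax-probability oracle (explicit formula, no reuse of
# package internals beyond standardize's definition).
proba_oracle <- function(x, fs, cfg) {
  mags <- dft_magnitude_oracle_fft(x, 60 * fs)[cfg$rate_range + 1]
  z <- if (stats::sd(mags) == 0) rep(0, length(mags))
       else (mags - mean(mags)) / stats::sd(mags)
  e <- exp(z - max(z))
  e / sum(e)
}

# fft-based magnitudes for the oracle (still independent of the package's
# amplitude_spectrum bookkeeping; base stats::fft only).
dft_magnitude_oracle_fft <- function(x, pad_to) {
  Mod(stats::fft(c(x, numeric(pad_to - length(x)))))
}

make_tmp_csv <- function(df) {
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  p
}
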
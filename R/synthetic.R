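# Run expr with a private RNG stream so generators are reproducible without
# clobbering the caller's random state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stepwise rate schedule
#'
#' @param rates Per-minute rate of each plateau.
#' @param durations Plateau durations in seconds (recycled).
#' @param ramp_s Transition time in seconds: the rate moves linearly from the
#'   previous plateau over the first `ramp_s` seconds of each plateau.
#'   0 (default) gives instantaneous steps (a metronome-style protocol);
#'   physiological drifts such as the hypoxia pulse response use a non-zero
#'   ramp.
#' @return Object of class `rate_schedule`.
#' @export
rate_schedule <- function(rates, durations, ramp_s = 0) {
  durations <- rep_len(durations, length(rates))
  stopifnot(all(durations > 0), all(rates >= 0), ramp_s >= 0,
            ramp_s <= min(durations))
  structure(list(rates = rates, durations = durations, ramp_s = ramp_s),
            class = "rate_schedule")
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat(sprintf("<rate_schedule> %d plateaus, %.0f s total, rates %g..%g\n",
              length(x$rates), sum(x$durations), min(x$rates), max(x$rates)))
  invisible(x)
}

#' Total duration of a schedule in seconds
#' @param schedule A [rate_schedule()].
#' @export
schedule_duration <- function(schedule) sum(schedule$durations)

#' Instantaneous scheduled rate
#'
#' Piecewise-constant rate at time `t` (times past the end hold the last
#' plateau).
#'
#' @param schedule A [rate_schedule()].
#' @param t Numeric vector of times in seconds.
#' @return Per-minute rates.
#' @export
schedule_rate_at <- function(schedule, t) {
  edges <- c(0, cumsum(schedule$durations))
  tc <- pmin(t, schedule_duration(schedule) - 1e-9)
  i <- findInterval(tc, edges, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i <- pmin(i, length(schedule$rates))
  r <- schedule$rates[i]
  ramp <- schedule$ramp_s %||% 0
  if (ramp > 0) {
    into <- tc - edges[i]              # time since the plateau started
    prev <- schedule$rates[pmax(i - 1L, 1L)]
    frac <- pmin(into / ramp, 1)
    r <- prev + frac * (r - prev)
  }
  r
}

#' Metronome-guided breathing protocol
#'
#' Emulates the paced-breathing protocol: an ascending staircase from 14 to
#' 26 BrPM in 2-BrPM increments capped by a 27 BrPM plateau, a descent back
#' to 14, a further descent to 4 BrPM in 2-BrPM decrements, and two abrupt
#' 5-BrPM jumps (4 -> 9 -> 14). Every plateau lasts at least one minute at
#' `scale = 1`.
#'
#' @param plateau_s Plateau duration in seconds (default 60).
#' @param scale Multiplier on all durations (e.g. 0.1 for quick tests).
#' @return A [rate_schedule()] with all rates in \[4, 27\] BrPM.
#' @export
make_metronome_schedule <- function(plateau_s = 60, scale = 1) {
  rates <- c(seq(14, 26, by = 2), 27,        # ascent
             seq(25, 15, by = -2), 14,       # descent to baseline
             seq(12, 4, by = -2),            # descent to 4
             9, 14)                          # two abrupt 5-BrPM jumps
  rate_schedule(rates, plateau_s * scale)
}

#' Simulated-altitude pulse protocol
#'
#' Emulates the hypoxia ramp protocol: pulse rate climbs across simulated
#' altitudes from resting values to 124 BPM, then recovers down to 45 BPM,
#' covering the 45--124 BPM range. Plateaus last 150 s at `scale = 1`
#' (the protocol holds each altitude for at least 2.5 min). Unlike the
#' metronome-paced breathing protocol, pulse rate responds to altitude
#' changes as a slow physiological drift, so plateaus are joined by 60 s
#' linear ramps (~0.15 BPM/s) rather than instantaneous steps.
#'
#' @param plateau_s Plateau duration in seconds (default 150).
#' @param scale Multiplier on all durations (including the ramp).
#' @param ramp_s Plateau-to-plateau transition time in seconds (default 60),
#'   scaled by `scale`.
#' @return A [rate_schedule()] spanning 45--124 BPM.
#' @export
make_altitude_schedule <- function(plateau_s = 150, scale = 1, ramp_s = 60) {
  ramp_s <- ramp_s * scale
  rates <- c(62, 70, 78, 86, 95, 105, 115, 124,
             110, 96, 82, 68, 55, 45)
  rate_schedule(rates, plateau_s * scale, ramp_s = min(ramp_s,
                                                       plateau_s * scale))
}

#' Noise and artifact specification for the simulator
#'
#' All amplitudes are relative to the unit-amplitude clean waveform.
#'
#' @param gaussian_sd Sd of additive white Gaussian sensor noise.
#' @param wander_amp,wander_freq Amplitude and frequency (Hz) of sinusoidal
#'   baseline wander.
#' @param spike_rate Transient artifact bursts per minute (Poisson).
#' @param spike_amp Burst amplitude in multiples of the signal amplitude.
#' @param spike_dur_s Burst duration in seconds.
#' @param resp_mod_depth Fractional amplitude modulation of the PPG pulse
#'   waveform by respiration.
#' @param resp_baseline_depth Additive respiratory baseline component of the
#'   PPG (the slow blood-volume swing that carries the respiratory band).
#' @param double_peak_ratio Secondary (dicrotic) peak amplitude relative to
#'   the primary, in \[0, 1\]; injects energy at twice the pulse frequency.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 0.3, wander_amp = 0.5,
                       wander_freq = 0.03, spike_rate = 1, spike_amp = 5,
                       spike_dur_s = 0.5, resp_mod_depth = 0.3,
                       resp_baseline_depth = 0.5, double_peak_ratio = 0.5) {
  spec <- list(gaussian_sd = gaussian_sd, wander_amp = wander_amp,
               wander_freq = wander_freq, spike_rate = spike_rate,
               spike_amp = spike_amp, spike_dur_s = spike_dur_s,
               resp_mod_depth = resp_mod_depth,
               resp_baseline_depth = resp_baseline_depth,
               double_peak_ratio = double_peak_ratio)
  stopifnot(all(unlist(spec) >= 0), double_peak_ratio <= 1)
  class(spec) <- "noise_spec"
  spec
}

#' Named noise presets
#'
#' `"clean"`: light sensor noise, no artifact bursts. `"moderate"`: realistic
#' resting-subject noise with occasional bursts (the default
#' [noise_spec()]). `"artifact"`: heavy, frequent motion bursts that
#' exercise the dissection and confidence machinery.
#'
#' @param name Preset name.
#' @return A [noise_spec()].
#' @export
noise_preset <- function(name = c("moderate", "clean", "artifact")) {
  name <- match.arg(name)
  switch(name,
    clean = noise_spec(gaussian_sd = 0.05, wander_amp = 0.3,
                       spike_rate = 0, spike_amp = 0),
    moderate = noise_spec(),
    artifact = noise_spec(gaussian_sd = 0.4, wander_amp = 0.6,
                          spike_rate = 4, spike_amp = 10, spike_dur_s = 1))
}

# Phase track (radians) for a per-minute rate schedule sampled at fs:
# phi' = 2*pi*rate(t)/60, integrated sample-wise so phase is continuous
# across plateau boundaries.
phase_track <- function(schedule, n, fs) {
  t <- (seq_len(n) - 1) / fs
  2 * pi * cumsum(schedule_rate_at(schedule, t) / 60) / fs
}

# Poisson-timed raised-cosine artifact bursts over n samples.
spike_train <- function(n, fs, rate_per_min, amp, dur_s) {
  out <- numeric(n)
  if (rate_per_min <= 0 || amp <= 0) return(out)
  k <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (k == 0) return(out)
  starts <- sort(stats::runif(k, 0, n / fs - dur_s))
  w <- max(2, round(dur_s * fs))
  burst <- 0.5 * (1 - cos(2 * pi * seq_len(w) / (w + 1)))  # raised cosine
  for (s in starts) {
    i0 <- round(s * fs) + 1
    idx <- i0:min(n, i0 + w - 1)
    out[idx] <- out[idx] + sample(c(-1, 1), 1) * amp * burst[seq_along(idx)]
  }
  out
}

#' Simulate dual-channel PPG
#'
#' Phenomenological PPG model: a quasi-periodic pulse waveform
#' `sin(phi) + double_peak_ratio * sin(2*phi + pi/4)` whose instantaneous
#' frequency follows the pulse-rate schedule, amplitude-modulated and
#' baseline-shifted by respiration, plus baseline wander, white noise and
#' Poisson-timed artifact bursts. The IR channel carries the same clean
#' waveform scaled by 0.8 with independent sensor noise (bursts and wander
#' are common-mode motion and shared). Deterministic for a fixed seed.
#'
#' @param schedule_pr Pulse-rate [rate_schedule()].
#' @param schedule_rr Respiratory [rate_schedule()] or `NULL` (no
#'   respiratory modulation).
#' @param dur Duration in seconds (default: full `schedule_pr`).
#' @param fs Sampling rate in Hz (default 400).
#' @param noise A [noise_spec()].
#' @param seed RNG seed.
#' @return Named list of `signal_channel`s `red` and `ir`.
#' @export
gen_ppg <- function(schedule_pr, schedule_rr = NULL, dur = NULL, fs = 400,
                    noise = noise_spec(), seed = 1) {
  if (is.null(dur)) dur <- schedule_duration(schedule_pr)
  stopifnot(dur <= schedule_duration(schedule_pr))
  n <- round(dur * fs)
  with_local_seed(seed, {
    phi <- phase_track(schedule_pr, n, fs)
    clean <- sin(phi) + noise$double_peak_ratio * sin(2 * phi + pi / 4)
    if (!is.null(schedule_rr)) {
      psi <- phase_track(schedule_rr, n, fs)
      clean <- clean * (1 + noise$resp_mod_depth * sin(psi)) +
        noise$resp_baseline_depth * sin(psi)
    }
    t <- (seq_len(n) - 1) / fs
    wander <- noise$wander_amp * sin(2 * pi * noise$wander_freq * t +
                                       stats::runif(1, 0, 2 * pi))
    spikes <- spike_train(n, fs, noise$spike_rate, noise$spike_amp,
                          noise$spike_dur_s)
    red <- clean + wander + spikes +
      stats::rnorm(n, sd = noise$gaussian_sd)
    ir <- 0.8 * (clean + spikes) + wander +
      stats::rnorm(n, sd = noise$gaussian_sd)
    list(red = signal_channel("red", red, fs),
         ir = signal_channel("ir", ir, fs))
  })
}

#' Simulate neck accelerometer Y/Z channels
#'
#' Each axis carries a static gravity offset plus a sinusoidal breathing
#' motion at the scheduled respiratory rate (phase-shifted between axes),
#' baseline wander, white noise and Poisson-timed motion bursts.
#'
#' @param schedule_rr Respiratory [rate_schedule()].
#' @param dur Duration in seconds (default: full schedule).
#' @param fs Sampling rate in Hz (default 100).
#' @param noise A [noise_spec()].
#' @param seed RNG seed.
#' @return Named list of `signal_channel`s `acc_y` and `acc_z`.
#' @export
gen_acc <- function(schedule_rr, dur = NULL, fs = 100,
                    noise = noise_spec(), seed = 1) {
  if (is.null(dur)) dur <- schedule_duration(schedule_rr)
  stopifnot(dur <= schedule_duration(schedule_rr))
  n <- round(dur * fs)
  with_local_seed(seed + 1000L, {
    psi <- phase_track(schedule_rr, n, fs)
    t <- (seq_len(n) - 1) / fs
    wander <- noise$wander_amp * sin(2 * pi * noise$wander_freq * t +
                                       stats::runif(1, 0, 2 * pi))
    spikes <- spike_train(n, fs, noise$spike_rate, noise$spike_amp,
                          noise$spike_dur_s)
    y <- 0.1 + sin(psi) + wander + spikes +
      stats::rnorm(n, sd = noise$gaussian_sd)
    z <- 0.98 + 0.8 * sin(psi + pi / 3) + 0.8 * wander + 0.8 * spikes +
      stats::rnorm(n, sd = noise$gaussian_sd)
    list(acc_y = signal_channel("acc_y", y, fs),
         acc_z = signal_channel("acc_z", z, fs))
  })
}

#' Simulate a full recording with ground truth
#'
#' Convenience wrapper producing the channels needed for a task plus the
#' 1 Hz ground-truth rate series the evaluation module consumes.
#'
#' @param task `"pulse"` or `"respiratory"`.
#' @param schedule Rate schedule for the task (defaults:
#'   [make_altitude_schedule()] / [make_metronome_schedule()]).
#' @param schedule_pr For the respiratory task, the pulse schedule carried by
#'   the PPG (default: constant 72 BPM).
#' @param noise A [noise_spec()].
#' @param seed RNG seed.
#' @return List with `channels` (named list of `signal_channel`s) and
#'   `truth` (data frame `time`, `rate`).
#' @export
simulate_recording <- function(task = c("respiratory", "pulse"),
                               schedule = NULL, schedule_pr = NULL,
                               noise = noise_preset("moderate"), seed = 1) {
  task <- match.arg(task)
  if (task == "pulse") {
    schedule <- schedule %||% make_altitude_schedule()
    ch <- gen_ppg(schedule, schedule_rr = NULL, noise = noise, seed = seed)
  } else {
    schedule <- schedule %||% make_metronome_schedule()
    dur <- schedule_duration(schedule)
    schedule_pr <- schedule_pr %||% rate_schedule(72, dur)
    ch <- c(gen_ppg(schedule_pr, schedule_rr = schedule, dur = dur,
                    noise = noise, seed = seed),
            gen_acc(schedule, noise = noise, seed = seed))
  }
  tt <- seq(0, schedule_duration(schedule) - 1)
  list(channels = ch,
       truth = data.frame(time = tt, rate = schedule_rate_at(schedule, tt)),
       schedule = schedule)
}
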
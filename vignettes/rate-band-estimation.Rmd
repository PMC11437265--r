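---
title: "Rate-band vital-sign estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-band vital-sign estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalband)
```

## The estimation problem

A neck-worn sensor patch provides two photoplethysmography channels (Red
and IR light) sampled at 400 Hz and a triaxial accelerometer sampled at
100 Hz. Both pulse rate (PR, beats per minute) and respiratory rate (RR,
breaths per minute) leave spectral signatures in these signals: the pulse
as a 0.75–2.1 Hz quasi-periodic PPG oscillation, breathing as a 0.07–0.45 Hz
component in the PPG baseline/amplitude and in the anteroposterior motion of
the neck. Neck signals are harder than finger or wrist signals — the site
moves with speech, swallowing and posture, and the PPG waveform routinely
carries a secondary (dicrotic-related) peak — so a plain band-pass plus peak
pick performs poorly. The framework in this package addresses that with
three ideas:

1. **softmax spectral probabilities** per 30-s window, turning the amplitude
   spectrum into a sharply-peaked probability over integer per-minute rates;
2. **recursive, artifact-aware dominance scoring**, which dissects a window
   around localized amplitude excursions and scores only its clean parts,
   discounted by recursion depth;
3. an **EWMA-driven band tracker** that smooths per-band evidence over time
   and emits interval ("rate band") estimates with confidence gating, plus a
   point value only when it falls inside the band.

## Processing pipeline

Estimation operates on a 30-s window sliding by 1 s; one estimate is
produced per second, timestamped at the window end so the tracker is causal
(the window vs. centre anchoring is not externally constrained; the causal
choice matches a monitoring use case).

**Pulse preprocessing** (per window, Red and IR): anti-aliased decimation
400→100 Hz; 0.05-s median despiking; first-order Butterworth band-pass
[0.5, 4] Hz; per-channel standardization; sample-wise summation of the two
channels; subtraction of a Savitzky–Golay baseline (order 2, 1.6-s window);
final standardization.

**Respiratory preprocessing** (PPG Red/IR or accelerometer Y/Z): each full
channel stream is band-passed [0.1, 1] Hz (first order) *before* windowing,
then per window: Savitzky–Golay smoothing (order 2, 2 s), standardization,
channel summation, a second identical smoothing, a first-difference
derivative (×fs, first value repeated) that suppresses residual baseline,
and standardization. The accelerometer X axis is never consumed: breathing
motion at this sensor site projects almost entirely on Y and Z.

Numerical choices worth recording:

* All IIR filters run forward–backward (zero phase). Spectral magnitudes are
  phase-insensitive, and zero-phase filtering avoids window-edge group-delay
  asymmetry. Channels are demeaned on entry so filter edge transients do not
  depend on the sensor's DC offset; this also makes the pulse pipeline
  exactly invariant to per-channel affine rescaling.
* Savitzky–Golay windows are specified in seconds and converted to the
  nearest odd sample count (1.6 s @ 100 Hz → 161; 2 s @ 100 Hz → 201).
  Coefficients come from `signal::sgolay`; the smoother applies the central
  row by FFT convolution with reflect padding, which is orders of magnitude
  faster than re-deriving the full projection matrix per window and agrees
  with `signal::sgolayfilt` away from the edges (tested).
* Degenerate (constant) windows propagate as all-zero segments; the
  standardization rule maps zero-variance input to zeros, and the softmax of
  a zero spectrum is the uniform distribution, which the dominance floor
  then discards.

## Spectral probabilities

Every (sub-)segment is zero-padded to exactly `60 * fs` samples before the
DFT, so bin spacing is exactly one per-minute unit and each integer rate in
the task range ([0, 240] BPM / [0, 60] BrPM, i.e. [0, 4] / [0, 1] Hz) maps
to one bin with no rounding collisions, regardless of the sub-segment's
length. In-range magnitudes are standardized (mean/sd over in-range bins
only) and softmaxed, so probabilities sum to one, are invariant to overall
signal scale, and concentrate on dominant components; weak components
typically fall below 0.1. The padding gives half-bin-resolution leakage
(a tone's immediate neighbours receive up to ~2/π of its peak), which is
harmless here: the band translation aggregates neighbours anyway.

## Dominance scores

A standardized segment with samples beyond ±3 is dissected: maximal
deviation-free runs of at least 5 s are re-standardized and scored
recursively (level + 1), and their probability estimates are accumulated
with weight 1/level for every rate with probability ≥ 0.1. Recursion stops
at depth 20 or when no flank reaches 5 s, in which case the segment
contributes its own (possibly contaminated) estimate at the current level —
a deliberate fallback so every timestep produces scores; the EWMA smoothing
and confidence gate absorb the contamination. A parent whose flanks are
accepted does not itself contribute. Deviation runs carry no guard margin
(the margin-free rule keeps the dissection parameter-free). For multimodal
respiratory estimation, PPG- and accelerometer-derived scores from the same
timestep are summed rate-wise.

## The tracker

Per timestep, with task parameters slack (5 BPM / 3 BrPM), α = 0.3 and
threshold 0.1:

1. *(pulse only)* **double-peak adjustment**: if rates above the 75th
   percentile of the observed rate set sit within slack of twice its median,
   and the set's minimum is within slack of the last confident estimate (or
   none exists yet), those harmonic outliers' scores are halved.
2. the **point-rate candidate** is the dominance argmax (ties to the lower
   rate, biasing fundamentals over harmonics);
3. **band translation**: each observed rate's band
   `[r − ⌊slack/2⌋, r + ⌈slack/2⌉]` collects the scores inside it; rates not
   observed score zero. With slack 3 a band centred at 12 spans [11, 14];
   with slack 5 a centre R spans [R−2, R+3];
4. **EWMA update**: `ewma ← 0.3·curr + 0.7·ewma`. A single observation's
   influence stays above 2.5% for 7 timesteps;
5. **band selection**: at the first timestep, the EWMA argmax; afterwards the
   above-threshold rate nearest the previous band (ties: larger EWMA value,
   then lower rate), which enforces gradual, physiologically plausible
   trajectories;
6. **confidence**: unconfident when the above-threshold rate set spreads
   beyond the slack on *both* sides of its median (25th/75th percentiles,
   linear interpolation over the unweighted rate values); an `or` variant is
   exposed as a configuration switch. Only confident timesteps emit output;
   the point value is attached only when it lies inside the band.

Before the first window the EWMA vector is seeded with a normal prior over
rates (pulse: mean 80, sd 20; respiratory: mean 14, sd 4) rescaled to unit
maximum. The rescaling is a design choice the framework's description leaves
open: a raw density with sd 20 peaks near 0.02 and could never clear the 0.1
threshold, making the first pulse steps vacuously unconfident; with unit-max
scaling the thresholded prior spans roughly μ ± 2.15σ and decays out of
relevance within ~7 steps. When no rate clears the threshold the previous
band is carried internally (so "nearest to previous" stays defined) but no
output is emitted.

The band translation follows its defining equation literally: a rate absent
from the dominance map gets a zero band score even when its band overlaps
observed rates. Whether the harmonic adjustment runs before or after the
point-rate extraction is similarly unpinned externally; here it runs before,
so the argmax sees adjusted scores.

## Evaluation

Band-aware error is 0 inside the band and the distance to the nearest bound
outside (band [11, 14] vs truth 15 → 1). RMSE/MAE/error SD are computed on
emitted estimates only; the output percentage counts emitted over processed
windows (timesteps before the first full window are not in the
denominator); the within-margin percentage uses ±5 BPM / ±3 BrPM for values
and 2.5 / 1.5 beyond the bounds for bands. Bland–Altman limits of agreement
use a components-of-variance decomposition for repeated measurements per
subject: between/within variance from the one-way ANOVA mean squares with
the n0 correction for unequal group sizes, negative estimates truncated at
zero, LoA = bias ± 1.96·√(σ²b + σ²w). With one subject this reduces exactly
to the classical formula. The difference convention is estimate − reference
throughout, and estimates are paired to the nearest reference timestamp
within 1 s.

## The synthetic generator

No recordings are distributable, so the package ships a phenomenological
simulator that reproduces the *spectral* structure the framework consumes —
not hemodynamics. PPG: `sin φ + r·sin(2φ + π/4)` with phase integrated from
the pulse schedule (r = 0.5 by default, a visible double peak that exercises
the harmonic adjustment), amplitude-modulated by respiration (depth 0.3) and
carrying an additive respiratory baseline component (depth 0.5) — the slow
blood-volume swing that actually survives the [0.1, 1] Hz band-pass, since
pure amplitude-modulation sidebands sit at carrier ± rate, outside that
band. IR is the same clean waveform scaled 0.8 with independent sensor
noise; wander and artifact bursts are common-mode. Accelerometer Y/Z carry
gravity offsets plus phase-shifted breathing sinusoids. Artifacts: sinusoidal
baseline wander (0.03 Hz), white noise, and Poisson-timed raised-cosine
bursts. Three presets are fixed: `clean` (sd 0.05, no bursts), `moderate`
(sd 0.3, 1 burst/min at 5× amplitude), `artifact` (sd 0.4, 4 bursts/min at
10×, 1 s long). All randomness flows from one seed through a private RNG
stream, so every dataset is bit-reproducible.

Two protocol generators mirror the study designs. The paced-breathing
staircase covers 4–27 BrPM: +2-BrPM steps from 14 to 26 capped by a 27
plateau (27 is unreachable from 14 in pure 2-steps, so the ascent ends with
a +1 step), a descent to 14 and on to 4, and two abrupt 5-BrPM jumps
(4→9→14), every plateau 60 s. Breathing follows the metronome, so these
steps are instantaneous. The hypoxia pulse protocol spans 45–124 BPM with
150-s plateaus joined by 60-s linear ramps: pulse rate responds to altitude
as a slow physiological drift (~0.15 BPM/s here), not a step. An early
staircase variant with instantaneous 8–14 BPM jumps mostly measured the
trailing-window lag against a stepped truth — a property of the test signal,
not of the estimator — which is why ramped transitions are the generator's
definition of this protocol.

What passing on these signals does **not** show: robustness to real
pulse-waveform morphology (skewed systolic upstrokes, variable dicrotic
timing), heart-rate variability within a window, posture-dependent coupling
changes, or sensor saturation. The generator's artifacts are amplitude
excursions; artifacts that alter frequency content without leaving the ±3
standardized band are invisible to the dissection step here as they would be
on real data.

## Verification scale and observed behaviour

The test suite runs the full protocols at study scale (respiratory
staircase ≈ 21 min, pulse ramp ≈ 35 min of signal; about 1200 and 2100
windows per run) over three seeds, in a few minutes of compute. On the
moderate preset the PPG+accelerometer respiratory chain keeps well over 90%
of emitted values within ±3 BrPM, and the pulse chain over 90% within
±5 BPM; on the heavy-artifact preset the fused respiratory accuracy is at
least that of either single modality. The acceptance script
(`scripts/acceptance.R`) recomputes the worked band-error examples and the
EWMA influence-decay count from the installed package.

## Known limitations

* **Low pulse rates harmonic-lock.** Near 45 BPM the 1.6-s Savitzky–Golay
  baseline subtraction attenuates the 0.75 Hz fundamental enough that the
  second harmonic dominates the dominance map outright; with no fundamental
  mass left above the 0.1 floor, the halving adjustment cannot rescue it and
  the tracker settles at twice the true rate until the rate rises again.
  This is visible on the synthetic hypoxia ramp's lowest plateau and bounds
  the usable range from below.
* Pulse estimation from the accelerometer is unsupported by design (the
  neck accelerometer resolves breathing motion, not the pulse), and the
  estimator assumes a single subject per recording stream.
* The dissection reacts to amplitude deviations only; band-limited noise
  that stays within ±3 standard deviations is handled solely by the EWMA
  and the confidence gate.
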
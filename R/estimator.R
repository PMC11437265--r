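#' Normal prior over candidate rates
#'
#' The EWMA vector is seeded, before the first window, with a normal density
#' over the integer rate grid centred on the task's resting-population prior
#' (pulse: mean 80, sd 20 BPM; respiratory: mean 14, sd 4 BrPM) and rescaled
#' to unit maximum. Unit-max scaling keeps the thresholded support of the
#' prior meaningful: values exceed the 0.1 threshold on roughly
#' `mu0 +/- 2.15 * sigma0` (solving `exp(-z^2/2) = 0.1`), whereas a raw
#' density with sd 20 would peak at ~0.02 and never clear the threshold.
#'
#' @param cfg A [task_config()].
#' @return Numeric vector over `cfg$rate_range` with maximum 1 at the rate
#'   nearest `mu0`.
#' @export
prior_distribution <- function(cfg) {
  d <- stats::dnorm(cfg$rate_range, cfg$mu0, cfg$sigma0)
  d / max(d)
}

#' Initial EWMA tracker state
#'
#' @param cfg A [task_config()].
#' @return Object of class `ewma_state`: per-rate EWMA vector (initialised to
#'   the prior), previous band centre, last confident rate, timestep index.
#' @export
ewma_state <- function(cfg) {
  structure(list(ewma = prior_distribution(cfg),
                 prev_band = NA_integer_,
                 last_confident = NA_integer_,
                 t = 0L),
            class = "ewma_state")
}

#' Harmonic (double-peak) adjustment of pulse dominance scores
#'
#' The secondary peak of the PPG pulse waveform injects energy at twice the
#' true pulse frequency. When the observed rate set contains upper outliers
#' near twice its median (within the slack), and its minimum is consistent
#' with the last confident estimate (or none exists yet), the dominance
#' scores of those outlier rates are halved. Applied for the pulse task only.
#'
#' @param ds `dominance_scores`.
#' @param last_confident Last confidently estimated rate, or `NA`.
#' @param cfg A [task_config()] with `task = "pulse"`.
#' @return Possibly adjusted `dominance_scores`.
#' @export
double_peak_adjustment <- function(ds, last_confident, cfg) {
  if (cfg$task != "pulse" || length(ds) < 2) return(ds)
  r <- sort(ds_rates(ds))
  m <- stats::median(r)
  p75 <- unname(stats::quantile(r, 0.75, type = 7))
  h2 <- r[r > p75 & abs(r - 2 * m) <= cfg$slack]
  if (!length(h2)) return(ds)
  b <- is.na(last_confident) || abs(min(r) - last_confident) <= cfg$slack
  if (!b) return(ds)
  out <- unclass(ds)
  out[as.character(h2)] <- out[as.character(h2)] / 2
  structure(out, class = "dominance_scores")
}

#' Per-band current scores (rate-band translation)
#'
#' Translates per-rate dominance scores into per-band scores: for every rate
#' present in the score map, the scores of all rates inside its variation
#' band `[Rate - floor(slack/2), Rate + ceiling(slack/2)]` are summed; rates
#' not themselves present in the map score 0.
#'
#' @param ds `dominance_scores`.
#' @param cfg A [task_config()].
#' @return Dense numeric vector over `cfg$rate_range`.
#' @export
band_scores <- function(ds, cfg) {
  curr <- numeric(length(cfg$rate_range))
  if (!length(ds)) return(curr)
  rmin <- min(cfg$rate_range); rmax <- max(cfg$rate_range)
  lo_off <- floor(cfg$slack / 2); hi_off <- ceiling(cfg$slack / 2)
  vals <- unclass(ds)
  rates <- ds_rates(ds)
  dense <- numeric(rmax - rmin + 1)
  dense[rates - rmin + 1] <- vals
  for (i in seq_along(rates)) {
    lo <- max(rmin, rates[i] - lo_off)
    hi <- min(rmax, rates[i] + hi_off)
    curr[rates[i] - rmin + 1] <- sum(dense[(lo - rmin + 1):(hi - rmin + 1)])
  }
  curr
}

#' EWMA update of the per-rate vector
#'
#' `ewma <- alpha * curr + (1 - alpha) * ewma`, element-wise. With the
#' default `alpha = 0.3` a single observation's influence decays
#' geometrically and stays above 2.5% for seven consecutive timesteps.
#'
#' @param prev,curr Equal-length numeric vectors.
#' @param cfg A [task_config()] (supplies `alpha`).
#' @return Updated vector.
#' @export
ewma_update <- function(prev, curr, cfg) {
  stopifnot(length(prev) == length(curr))
  cfg$alpha * curr + (1 - cfg$alpha) * prev
}

# Rates whose EWMA value exceeds the threshold.
h_rates <- function(ewma, cfg) cfg$rate_range[ewma > cfg$thresh]

#' Select the rate-band centre from the EWMA vector
#'
#' At the first timestep the band centre is the EWMA argmax. Afterwards it is
#' the above-threshold rate closest to the previous band centre (ties broken
#' by larger EWMA value, then by the lower rate), which keeps the band
#' trajectory smooth and biologically gradual. With no above-threshold rate,
#' `NA` is returned and the caller retains the previous band (unconfident).
#'
#' @param ewma Dense EWMA vector over `cfg$rate_range`.
#' @param state An `ewma_state` (previous band, timestep).
#' @param cfg A [task_config()].
#' @return Integer band centre or `NA`.
#' @export
select_band <- function(ewma, state, cfg) {
  hr <- h_rates(ewma, cfg)
  if (state$t <= 1L || is.na(state$prev_band)) {
    pool <- if (length(hr)) hr else cfg$rate_range
    vals <- ewma[match(pool, cfg$rate_range)]
    return(pool[which.max(vals)])  # which.max takes the first (lowest) on ties
  }
  if (!length(hr)) return(NA_integer_)
  vals <- ewma[match(hr, cfg$rate_range)]
  o <- order(abs(hr - state$prev_band), -vals, hr)
  hr[o[1]]
}

#' Confidence of the current EWMA distribution
#'
#' The estimate is confident unless the above-threshold rate set spreads
#' significantly beyond the slack around its median: unconfident iff the
#' distance from the median to the 25th percentile AND to the 75th percentile
#' (both computed over the unweighted rate values, linear interpolation) each
#' exceed the slack. An empty above-threshold set is unconfident.
#' `cfg$confidence_mode = "or"` switches to the one-sided variant.
#'
#' @param ewma Dense EWMA vector over `cfg$rate_range`.
#' @param cfg A [task_config()].
#' @return Logical.
#' @export
assess_confidence <- function(ewma, cfg) {
  hr <- h_rates(ewma, cfg)
  if (!length(hr)) return(FALSE)
  q <- unname(stats::quantile(hr, c(0.25, 0.5, 0.75), type = 7))
  lo <- q[2] - q[1]; hi <- q[3] - q[2]
  wide <- if (cfg$confidence_mode == "and") (lo > cfg$slack) && (hi > cfg$slack)
          else (lo > cfg$slack) || (hi > cfg$slack)
  !wide
}

band_bounds <- function(center, cfg) {
  c(low = center - floor(cfg$slack / 2),
    high = center + ceiling(cfg$slack / 2))
}

#' One tracker timestep
#'
#' Runs the full per-timestep estimation given a (modality-combined)
#' dominance-score map: harmonic adjustment (pulse only), point-rate
#' extraction (dominance argmax, ties to the lower rate), band translation,
#' EWMA update, band selection and confidence gating. The EWMA state always
#' updates; an output row is produced for every timestep, with
#' `confident = FALSE` marking suppressed estimates. The point rate value is
#' attached only when it lies inside the selected band, and the last
#' confident rate is remembered for the harmonic adjustment.
#'
#' @param ds `dominance_scores` for this timestep.
#' @param state An `ewma_state`.
#' @param cfg A [task_config()].
#' @param t Timestamp in seconds for the output row.
#' @return List with `estimate` (one-row data frame: `t`, `rate_value`,
#'   `band_center`, `band_low`, `band_high`, `confident`) and `state`.
#' @export
estimator_step <- function(ds, state, cfg, t = NA_real_) {
  state$t <- state$t + 1L
  if (cfg$task == "pulse")
    ds <- double_peak_adjustment(ds, state$last_confident, cfg)
  rv_est <- if (length(ds)) {
    r <- ds_rates(ds); v <- unclass(ds)
    o <- order(-v, r)
    r[o[1]]
  } else NA_integer_
  curr <- band_scores(ds, cfg)
  state$ewma <- ewma_update(state$ewma, curr, cfg)
  center <- select_band(state$ewma, state, cfg)
  if (is.na(center)) {
    confident <- FALSE
    center <- state$prev_band        # carried forward; may still be NA at t=1
  } else {
    confident <- assess_confidence(state$ewma, cfg)
  }
  state$prev_band <- center
  if (is.na(center)) {
    bounds <- c(low = NA_integer_, high = NA_integer_)
  } else {
    bounds <- band_bounds(center, cfg)
  }
  rate_value <- NA_integer_
  if (confident && !is.na(rv_est) &&
      rv_est >= bounds["low"] && rv_est <= bounds["high"])
    rate_value <- rv_est
  if (confident)
    state$last_confident <- if (!is.na(rate_value)) rate_value else center
  est <- data.frame(t = t, rate_value = rate_value,
                    band_center = center,
                    band_low = unname(bounds["low"]),
                    band_high = unname(bounds["high"]),
                    confident = confident)
  list(estimate = est, state = state)
}
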
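cfg_p <- task_config("pulse")
cfg_r <- task_config("respiratory")

ds_of <- function(...) {
  v <- c(...)
  structure(v, class = "dominance_scores")
}

test_that("the prior peaks at the population mean with unit maximum", {
  pp <- prior_distribution(cfg_p)
  expect_equal(cfg_p$rate_range[which.max(pp)], 80)
  expect_equal(max(pp), 1)
  # symmetry around the mean
  expect_equal(pp[cfg_p$rate_range == 80 + 7], pp[cfg_p$rate_range == 80 - 7])

  # respiratory: values exceed 0.1 on roughly mu +/- 2.15*sigma = [5, 23]
  pr <- prior_distribution(cfg_r)
  above <- cfg_r$rate_range[pr > 0.1]
  expect_equal(range(above), c(6, 22))  # integer rates inside [5.4, 22.6]
})

test_that("double-peak adjustment halves harmonic outliers per the percentile rule", {
  ds <- ds_of(`68` = 0.3, `70` = 0.5, `72` = 0.4, `140` = 0.45)
  # R = {68,70,72,140}: median 71, P75 = 89 (linear interpolation);
  # 140 > 89 and |140 - 142| = 2 <= 5; |68 - 69| = 1 <= 5 -> halve DS[140]
  adj <- double_peak_adjustment(ds, last_confident = 69, cfg_p)
  expect_equal(unclass(adj)[["140"]], 0.225)
  expect_equal(unclass(adj)[["70"]], 0.5)

  # no rate near twice the median -> unchanged
  ds2 <- ds_of(`68` = 0.3, `70` = 0.5, `72` = 0.4)
  expect_equal(unclass(double_peak_adjustment(ds2, 69, cfg_p)),
               unclass(ds2))

  # min(R) far from the last confident rate -> condition B fails
  adj3 <- double_peak_adjustment(ds, last_confident = 100, cfg_p)
  expect_equal(unclass(adj3), unclass(ds))

  # cold start (no confident estimate yet): harmonic check alone applies
  adj4 <- double_peak_adjustment(ds, last_confident = NA, cfg_p)
  expect_equal(unclass(adj4)[["140"]], 0.225)

  # never applied for the respiratory task
  ds_r <- ds_of(`7` = 0.4, `14` = 0.5)
  expect_equal(unclass(double_peak_adjustment(ds_r, 14, cfg_r)),
               unclass(ds_r))
})

test_that("band scores implement the gated band sum (worked example + brute force)", {
  # respiratory slack 3: band centred at Rate spans [Rate-1, Rate+2]
  ds <- ds_of(`12` = 0.5, `14` = 0.2)
  curr <- band_scores(ds, cfg_r)
  expect_equal(curr[cfg_r$rate_range == 12], 0.7)  # sums r in [11, 14]
  expect_equal(curr[cfg_r$rate_range == 14], 0.2)  # r in [13, 16]
  expect_equal(curr[cfg_r$rate_range == 13], 0)    # 13 not an observed rate
  expect_true(all(band_scores(dominance_scores(), cfg_r) == 0))

  # brute-force double-loop oracle on random sparse maps
  set.seed(21)
  for (i in 1:50) {
    cfg <- if (i %% 2) cfg_r else cfg_p
    k <- sample(1:8, 1)
    rates <- sort(sample(cfg$rate_range, k))
    vals <- stats::runif(k, 0.05, 1)
    ds <- structure(stats::setNames(vals, rates), class = "dominance_scores")
    curr <- band_scores(ds, cfg)
    lo <- floor(cfg$slack / 2); hi <- ceiling(cfg$slack / 2)
    oracle <- vapply(cfg$rate_range, function(Rate) {
      if (!Rate %in% rates) return(0)
      s <- 0
      for (r in (Rate - lo):(Rate + hi))
        if (r %in% rates) s <- s + vals[match(r, rates)]
      s
    }, numeric(1))
    expect_equal(curr, oracle, tolerance = 1e-12)
  }
})

test_that("the EWMA update is a convex combination with geometric memory", {
  prev <- numeric(61); curr <- numeric(61); curr[15] <- 1
  out <- ewma_update(prev, curr, cfg_r)
  expect_equal(out[15], 0.3)
  expect_equal(ewma_update(prev, prev, cfg_r), prev)
  v <- prev; v[15] <- 0.8
  expect_equal(ewma_update(v, v, cfg_r), v)   # fixed point

  # impulse response: contribution at lag k is 0.3 * 0.7^k
  w <- numeric(61); w <- ewma_update(w, curr, cfg_r)
  lags <- c(w[15])
  for (k in 1:10) {
    w <- ewma_update(w, numeric(61), cfg_r)
    lags <- c(lags, w[15])
  }
  expect_equal(lags, 0.3 * 0.7^(0:10), tolerance = 1e-12)
})

test_that("band selection follows argmax at start then nearest-band tracking", {
  st <- ewma_state(cfg_p); st$t <- 1L
  ew <- prior_distribution(cfg_p)
  expect_equal(select_band(ew, st, cfg_p), 80)

  st2 <- ewma_state(cfg_p); st2$t <- 5L; st2$prev_band <- 70L
  ew2 <- numeric(241)
  ew2[c(60, 72, 140) + 1] <- c(0.5, 0.4, 0.9)
  expect_equal(select_band(ew2, st2, cfg_p), 72)

  # tie on distance broken by the larger EWMA value
  ew3 <- numeric(241)
  ew3[c(68, 72) + 1] <- c(0.3, 0.5)
  expect_equal(select_band(ew3, st2, cfg_p), 72)
  ew3[c(68, 72) + 1] <- c(0.5, 0.3)
  expect_equal(select_band(ew3, st2, cfg_p), 68)

  # nothing above threshold -> NA (band carried by the caller)
  expect_true(is.na(select_band(numeric(241), st2, cfg_p)))
})

test_that("confidence reflects the spread of above-threshold rates", {
  mk <- function(rates, n = 241) { v <- numeric(n); v[rates + 1] <- 1; v }
  expect_true(assess_confidence(mk(70:73), cfg_p))
  # 61 consecutive rates: median 90, P25 75, P75 105 -> both spreads 15 > 5
  expect_false(assess_confidence(mk(60:120), cfg_p))
  expect_false(assess_confidence(numeric(241), cfg_p))
  # one-sided spread: confident under "and", unconfident under "or"
  # (sorted set 70..80, 120..123: median 77, P25 73.5, P75 100)
  asym <- mk(c(70:80, 120:123))
  expect_true(assess_confidence(asym, cfg_p))
  cfg_or <- task_config("pulse", confidence_mode = "or")
  expect_false(assess_confidence(asym, cfg_or))
})

test_that("band bounds implement the floor/ceiling slack split", {
  st <- ewma_state(cfg_r)
  ds <- ds_of(`12` = 0.9)
  out <- estimator_step(ds, st, cfg_r, t = 30)
  for (i in 1:9) out <- estimator_step(ds, out$state, cfg_r, t = 30 + i)
  e <- out$estimate
  expect_equal(e$band_center, 12)
  expect_equal(c(e$band_low, e$band_high), c(11, 14))  # slack 3
  # pulse slack 5: centre R spans [R-2, R+3]
  stp <- ewma_state(cfg_p)
  dsp <- ds_of(`80` = 0.9)
  outp <- estimator_step(dsp, stp, cfg_p, t = 30)
  expect_equal(c(outp$estimate$band_low, outp$estimate$band_high),
               c(78, 83))
})

test_that("a steady tone stream converges to a confident in-band value", {
  st <- ewma_state(cfg_p)
  x <- tone_segment(72)
  ds <- get_dominance_scores(x, 100, cfg_p)
  est <- NULL
  for (i in 1:15) {
    out <- estimator_step(ds, st, cfg_p, t = 29 + i)
    st <- out$state
    est <- out$estimate
  }
  expect_true(est$confident)
  expect_equal(est$rate_value, 72)
  expect_lte(est$band_low, 72); expect_gte(est$band_high, 72)
  expect_equal(st$last_confident, 72)
})

test_that("an argmax outside the selected band yields a band-only estimate", {
  st <- ewma_state(cfg_r)
  # settle the band near 14 first
  ds14 <- ds_of(`14` = 0.9)
  for (i in 1:10) { out <- estimator_step(ds14, st, cfg_r); st <- out$state }
  # now a bimodal map whose argmax (40) sits far outside the tracked band
  dsbi <- ds_of(`13` = 0.3, `14` = 0.5, `15` = 0.3, `40` = 0.9)
  out <- estimator_step(dsbi, st, cfg_r)
  e <- out$estimate
  expect_true(e$confident)
  expect_equal(e$band_center, 14)
  expect_true(is.na(e$rate_value))
})

test_that("with no dominance mass the EWMA decays into unconfident silence", {
  st <- ewma_state(cfg_r)
  emitted <- logical(0)
  for (i in 1:40) {
    out <- estimator_step(dominance_scores(), st, cfg_r)
    st <- out$state
    emitted <- c(emitted, out$estimate$confident)
  }
  expect_false(any(tail(emitted, 20)))
  expect_true(all(st$ewma < 0.1))
})
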
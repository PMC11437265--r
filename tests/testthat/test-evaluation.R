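cfg_r <- task_config("respiratory")
cfg_p <- task_config("pulse")

test_that("band error is zero inside the band and distance-to-bound outside", {
  expect_equal(band_error(11, 14, 15), 1)
  expect_equal(band_error(11, 14, 12), 0)
  expect_equal(band_error(11, 14, 9), 2)
  expect_equal(band_error(11, 14, c(11, 14)), c(0, 0))
  # never worse than the distance to the band centre
  set.seed(4)
  for (i in 1:50) {
    ctr <- sample(5:50, 1)
    lo <- ctr - 1; hi <- ctr + 2
    truth <- stats::runif(1, 0, 60)
    expect_lte(band_error(lo, hi, truth), abs(truth - ctr))
  }
  # degenerate band: coincides with absolute error
  expect_equal(band_error(12, 12, 15.5), abs(15.5 - 12))
})

make_records <- function(rv, lo, hi, conf, ref) {
  data.frame(t = seq_along(rv) + 29, rate_value = rv, band_center = lo + 1,
             band_low = lo, band_high = hi, confident = conf,
             reference = ref)
}

test_that("agreement summary matches hand-computed metrics", {
  # perfect tracking
  rec <- make_records(rep(14L, 10), 13, 16, TRUE, rep(14, 10))
  rep1 <- summarize_agreement(rec, cfg_r, "value")
  expect_equal(rep1$rmse, 0); expect_equal(rep1$mae, 0)
  expect_equal(rep1$error_std, 0)
  expect_equal(rep1$pct_output, 100); expect_equal(rep1$pct_within, 100)
  expect_equal(c(rep1$loa_low, rep1$bias, rep1$loa_high), c(0, 0, 0))

  # half the timesteps suppressed
  rec2 <- rec; rec2$confident[1:5] <- FALSE; rec2$rate_value[1:5] <- NA
  expect_equal(summarize_agreement(rec2, cfg_r, "value")$pct_output, 50)

  # five emitted records with known errors: d = c(1, -2, 0, 3, -1)
  rec3 <- make_records(c(15L, 12L, 14L, 17L, 13L), 13, 16, TRUE,
                       rep(14, 5))
  rep3 <- summarize_agreement(rec3, cfg_r, "value")
  d <- c(1, -2, 0, 3, -1)
  expect_equal(rep3$rmse, sqrt(mean(d^2)))
  expect_equal(rep3$mae, mean(abs(d)))
  expect_equal(rep3$error_std, stats::sd(d))
  expect_equal(rep3$bias, mean(d))
  expect_equal(rep3$pct_within, 100)   # all |d| <= 3 BrPM
})

test_that("band mode scores bands and coincides with value mode when degenerate", {
  rec <- make_records(c(15L, 12L), c(11, 11), c(14, 14), TRUE, c(15, 12))
  repb <- summarize_agreement(rec, cfg_r, "band")
  expect_equal(repb$mae, mean(c(band_error(11, 14, 15),
                                band_error(11, 14, 12))))
  # degenerate band low = high = RV
  rec2 <- make_records(c(15L, 12L), c(15, 12), c(15, 12), TRUE, c(14, 14))
  repb2 <- summarize_agreement(rec2, cfg_r, "band")
  repv2 <- summarize_agreement(rec2, cfg_r, "value")
  expect_equal(repb2$rmse, repv2$rmse)
  expect_equal(repb2$mae, repv2$mae)
})

test_that("rate-value output percentage never exceeds band output percentage", {
  set.seed(31)
  rv <- sample(c(NA, 12L, 14L), 50, replace = TRUE)
  conf <- !is.na(rv) | stats::runif(50) < 0.5
  rec <- make_records(rv, 11, 14, conf, rep(13, 50))
  rec$rate_value[!rec$confident] <- NA
  pv <- summarize_agreement(rec, cfg_r, "value")$pct_output
  pb <- summarize_agreement(rec, cfg_r, "band")$pct_output
  expect_lte(pv, pb)
})

test_that("zero emitted estimates yields a flagged empty report", {
  rec <- make_records(rep(NA_integer_, 5), 11, 14, FALSE, rep(14, 5))
  rep0 <- summarize_agreement(rec, cfg_r, "value")
  expect_equal(rep0$pct_output, 0)
  expect_true(is.na(rep0$rmse))
})

test_that("single-subject limits of agreement equal the classical formula", {
  set.seed(8)
  d <- stats::rnorm(200, mean = 0.5, sd = 2)
  ba <- bland_altman_cov(d)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * stats::sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * stats::sd(d))
  # identical zero differences
  ba0 <- bland_altman_cov(rep(0, 10))
  expect_equal(c(ba0$loa_low, ba0$bias, ba0$loa_high), c(0, 0, 0))
})

test_that("components-of-variance recovers known variance components", {
  set.seed(99)
  k <- 20; n <- 50
  subj <- rep(seq_len(k), each = n)
  d <- rep(stats::rnorm(k, 0, 1), each = n) + stats::rnorm(k * n, 0, 2)
  ba <- bland_altman_cov(d, subj)
  half <- (ba$loa_high - ba$loa_low) / 2
  expect_equal(half, 1.96 * sqrt(5), tolerance = 0.1)
  # monotone in the components: inflating within-subject noise widens LoA
  d2 <- d + stats::rnorm(k * n, 0, 2)
  ba2 <- bland_altman_cov(d2, subj)
  expect_gt(ba2$loa_high - ba2$loa_low, ba$loa_high - ba$loa_low)
})

test_that("unequal group sizes use the n0 correction (direct formula oracle)", {
  set.seed(12)
  ni <- c(5, 20, 35)
  subj <- rep(1:3, times = ni)
  d <- rep(c(-1, 0, 1), times = ni) + stats::rnorm(sum(ni))
  ba <- bland_altman_cov(d, subj)
  # independent hand computation of the one-way ANOVA decomposition
  N <- sum(ni); k <- 3
  gm <- mean(d)
  means <- tapply(d, subj, mean)
  ssb <- sum(ni * (means - gm)^2)
  ssw <- sum((d - means[as.character(subj)])^2)
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vb <- max(0, (msb - msw) / n0)
  expect_equal(ba$loa_high - ba$bias, 1.96 * sqrt(vb + msw),
               tolerance = 1e-9)
})

test_that("pairing respects the tolerance and attaches the reference", {
  est <- data.frame(t = c(30, 31, 35), rate_value = c(14L, 14L, 15L),
                    band_center = 14L, band_low = 13L, band_high = 16L,
                    confident = TRUE)
  ref <- data.frame(time = c(30.2, 31.1, 40), rate = c(14, 15, 16))
  expect_warning(pr <- pair_with_reference(est, ref), "no reference")
  expect_equal(nrow(pr), 2)
  expect_equal(pr$reference, c(14, 15))
})
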
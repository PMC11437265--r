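#' Band-aware absolute error
#'
#' Error of an interval (rate-band) estimate with respect to a reference
#' rate: 0 when the reference lies inside the band, otherwise the distance to
#' the nearest bound. A band of \[11, 14\] BrPM scores 0 against a reference
#' of 12 and 1 against a reference of 15.
#'
#' @param band_low,band_high Band bounds (inclusive), `band_low <= band_high`.
#' @param truth Reference rate(s).
#' @return Non-negative error(s), vectorised over all arguments.
#' @export
band_error <- function(band_low, band_high, truth) {
  stopifnot(all(band_low <= band_high))
  pmax(band_low - truth, truth - band_high, 0)
}

# Signed band error (estimate - reference convention): negative when the
# reference exceeds the upper bound (the estimate runs low).
band_error_signed <- function(band_low, band_high, truth) {
  ifelse(truth > band_high, band_high - truth,
         ifelse(truth < band_low, band_low - truth, 0))
}

#' Pair rate estimates with a reference series
#'
#' Matches each estimate row to the nearest reference timestamp within a
#' tolerance (default 1 s); unmatched rows are dropped with a warning.
#'
#' @param estimates Data frame from [estimate_rates()] /
#'   [read_estimates()].
#' @param reference Data frame with columns `time`, `rate` (see
#'   [read_rate_series()]).
#' @param tolerance_s Maximum pairing distance in seconds.
#' @param subject Optional subject identifier attached to every row.
#' @return `estimates` with columns `reference` (and `subject`) appended.
#' @export
pair_with_reference <- function(estimates, reference, tolerance_s = 1,
                                subject = NULL) {
  idx <- vapply(estimates$t, function(t) which.min(abs(reference$time - t)),
                integer(1))
  dist <- abs(reference$time[idx] - estimates$t)
  ok <- dist <= tolerance_s
  if (!all(ok))
    warning(sprintf("%d estimate rows had no reference within %g s",
                    sum(!ok), tolerance_s))
  out <- estimates[ok, , drop = FALSE]
  out$reference <- reference$rate[idx[ok]]
  if (!is.null(subject)) out$subject <- subject
  out
}

#' Agreement summary between estimates and reference rates
#'
#' Computes the band-aware evaluation statistics over a paired record set:
#' RMSE, MAE and error standard deviation on the emitted estimates (point
#' values in `mode = "value"`, band-aware errors in `mode = "band"`), the
#' percentage of timesteps with an emitted (confident) output, the
#' percentage of emitted outputs within the clinically acceptable margin
#' (pulse: +/-5 BPM for values, 2.5 BPM beyond the band bounds; respiratory:
#' +/-3 / 1.5 BrPM), and Bland-Altman bias and 95% limits of agreement
#' (components-of-variance when a `subject` column with multiple subjects is
#' present, classical otherwise).
#'
#' @param records Paired data frame from [pair_with_reference()]; must cover
#'   all processed timesteps, including suppressed ones.
#' @param cfg A [task_config()] (determines the clinical margins).
#' @param mode `"value"` (point estimates) or `"band"` (interval estimates).
#' @return Object of class `agreement_report`.
#' @export
summarize_agreement <- function(records, cfg, mode = c("value", "band")) {
  mode <- match.arg(mode)
  total <- nrow(records)
  if (mode == "value") {
    emitted <- records[records$confident & !is.na(records$rate_value), ,
                       drop = FALSE]
    err <- emitted$rate_value - emitted$reference
    margin <- if (cfg$task == "pulse") 5 else 3
  } else {
    emitted <- records[records$confident & !is.na(records$band_low), ,
                       drop = FALSE]
    err <- band_error_signed(emitted$band_low, emitted$band_high,
                             emitted$reference)
    margin <- if (cfg$task == "pulse") 2.5 else 1.5
  }
  n <- length(err)
  pct_output <- if (total > 0) 100 * n / total else 0
  if (n == 0) {
    rep <- list(rmse = NA_real_, mae = NA_real_, error_std = NA_real_,
                pct_output = 0, pct_within = 0,
                bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
                n_emitted = 0L, n_total = total, mode = mode,
                units = cfg$units, margin = margin)
    class(rep) <- "agreement_report"
    return(rep)
  }
  subj <- if ("subject" %in% names(emitted)) emitted$subject
          else rep("s1", n)
  ba <- if (n >= 2) bland_altman_cov(err, subj)
        else list(bias = mean(err), loa_low = NA_real_, loa_high = NA_real_)
  rep <- list(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    error_std = if (n >= 2) stats::sd(err) else NA_real_,
    pct_output = pct_output,
    pct_within = 100 * mean(abs(err) <= margin),
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    n_emitted = n, n_total = total, mode = mode,
    units = cfg$units, margin = margin)
  class(rep) <- "agreement_report"
  rep
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (%s mode, %s)\n", x$mode, x$units))
  cat(sprintf("  emitted %d / %d timesteps (%.1f%% output)\n",
              x$n_emitted, x$n_total, x$pct_output))
  if (x$n_emitted > 0) {
    cat(sprintf("  RMSE %.2f  MAE %.2f  STD %.2f %s\n",
                x$rmse, x$mae, x$error_std, x$units))
    cat(sprintf("  within +/-%g %s: %.1f%% of emitted outputs\n",
                x$margin, x$units, x$pct_within))
    cat(sprintf("  bias %.2f, 95%% LoA [%.2f, %.2f]\n",
                x$bias, x$loa_low, x$loa_high))
  }
  invisible(x)
}

#' Bland-Altman limits of agreement with components of variance
#'
#' Bias and 95% limits of agreement for paired differences with repeated
#' measurements per subject. The total variance of a difference is
#' decomposed into between-subject and within-subject components from the
#' one-way ANOVA mean squares (unequal group sizes handled by the standard
#' n0 correction); negative component estimates are truncated at zero.
#' `LoA = bias +/- 1.96 * sqrt(var_between + var_within)`. With a single
#' subject this reduces exactly to the classical `bias +/- 1.96 * sd`.
#'
#' @param d Numeric vector of paired differences (estimate - reference).
#' @param subject Subject identifier for each difference.
#' @return List: `bias`, `loa_low`, `loa_high`, `var_between`, `var_within`.
#' @export
bland_altman_cov <- function(d, subject = rep("s1", length(d))) {
  stopifnot(length(d) == length(subject))
  if (length(d) < 2) stop("need at least two paired differences")
  subject <- factor(subject)
  bias <- mean(d)
  k <- nlevels(subject)
  if (k == 1) {
    s <- stats::sd(d)
    return(list(bias = bias, loa_low = bias - 1.96 * s,
                loa_high = bias + 1.96 * s,
                var_between = 0, var_within = s^2))
  }
  fit <- stats::aov(d ~ subject)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  ni <- as.numeric(table(subject))
  N <- sum(ni)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vb <- max(0, (msb - msw) / n0)
  vw <- msw
  half <- 1.96 * sqrt(vb + vw)
  list(bias = bias, loa_low = bias - half, loa_high = bias + half,
       var_between = vb, var_within = vw)
}
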
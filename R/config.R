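#' Task configuration for rate estimation
#'
#' Bundles every tunable parameter of the estimation framework for one
#' measurement task. Defaults encode the published operating point of the
#' method: spectra are scored inside \[0, 4\] Hz for pulse (rates 0--240 BPM)
#' and \[0, 1\] Hz for respiratory (rates 0--60 BrPM); the clinical spread
#' allowance (`slack`) is 5 BPM / 3 BrPM; the EWMA memory is `alpha = 0.3`;
#' the EWMA/ probability threshold is 0.1.
#'
#' @param task `"pulse"` or `"respiratory"`.
#' @param slack Spread allowance in rate units; sizes the rate band
#'   (`[center - floor(slack/2), center + ceiling(slack/2)]`) and the
#'   confidence spread test.
#' @param mu0,sigma0 Mean and standard deviation (rate units) of the normal
#'   prior used to seed the EWMA vector before the first window.
#' @param alpha EWMA weight on the current window's band scores, in (0, 1].
#' @param thresh EWMA threshold above which a rate participates in band
#'   selection and the confidence test.
#' @param proba_floor Minimum softmax probability for a rate to contribute to
#'   dominance scores.
#' @param max_depth Maximum recursion depth of the dominance-score dissection.
#' @param min_subseg_s Minimum accepted sub-segment duration in seconds.
#' @param dev_bound Standardized-amplitude bound beyond which a sample is
#'   flagged as a deviation (artifact) during dissection.
#' @param rate_range Integer vector of candidate per-minute rates.
#' @param confidence_mode `"and"` (default: unconfident only when the spread
#'   exceeds the slack on both sides of the median) or `"or"`.
#'
#' @return An object of class `task_config` (a list).
#' @export
#' @examples
#' task_config("respiratory")$slack  # 3
task_config <- function(task = c("pulse", "respiratory"),
                        slack = NULL, mu0 = NULL, sigma0 = NULL,
                        alpha = 0.3, thresh = 0.1, proba_floor = 0.1,
                        max_depth = 20, min_subseg_s = 5, dev_bound = 3,
                        rate_range = NULL,
                        confidence_mode = c("and", "or")) {
  task <- match.arg(task)
  confidence_mode <- match.arg(confidence_mode)
  defaults <- if (task == "pulse") {
    list(slack = 5, mu0 = 80, sigma0 = 20, rate_range = 0:240,
         freq_range = c(0, 4), units = "BPM")
  } else {
    list(slack = 3, mu0 = 14, sigma0 = 4, rate_range = 0:60,
         freq_range = c(0, 1), units = "BrPM")
  }
  cfg <- list(
    task = task,
    slack = if (is.null(slack)) defaults$slack else slack,
    mu0 = if (is.null(mu0)) defaults$mu0 else mu0,
    sigma0 = if (is.null(sigma0)) defaults$sigma0 else sigma0,
    alpha = alpha, thresh = thresh, proba_floor = proba_floor,
    max_depth = max_depth, min_subseg_s = min_subseg_s,
    dev_bound = dev_bound,
    rate_range = if (is.null(rate_range)) defaults$rate_range
                 else as.integer(rate_range),
    freq_range = defaults$freq_range,
    units = defaults$units,
    confidence_mode = confidence_mode
  )
  stopifnot(cfg$alpha > 0, cfg$alpha <= 1, cfg$slack > 0,
            cfg$min_subseg_s > 0, cfg$max_depth >= 1)
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("Task configuration: %s rate (%s)\n", x$task, x$units))
  cat(sprintf("  rates %d..%d, slack %d, prior N(%g, %g)\n",
              min(x$rate_range), max(x$rate_range), x$slack, x$mu0, x$sigma0))
  cat(sprintf("  alpha %g, thresh %g, proba floor %g\n",
              x$alpha, x$thresh, x$proba_floor))
  cat(sprintf("  dissection: |z| > %g, min sub-segment %g s, max depth %d\n",
              x$dev_bound, x$min_subseg_s, x$max_depth))
  invisible(x)
}

#' Sliding window specification
#'
#' @param length_s Window length in seconds (default 30).
#' @param step_s Hop between consecutive windows in seconds (default 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 30, step_s = 1) {
  stopifnot(length_s > 0, step_s > 0, step_s <= length_s)
  structure(list(length_s = length_s, step_s = step_s), class = "window_spec")
}

#' Read a run configuration file
#'
#' Reads a YAML key/value file declaring per-channel sampling rates and task
#' parameters. Recognised top-level keys: `task`, `modalities`,
#' `channels` (map channel name -> fs in Hz), `window` (`length_s`, `step_s`)
#' and any [task_config()] argument.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `task_config`, `window`, `channels`,
#'   `modalities`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  task <- raw$task %||% "respiratory"
  tc_args <- raw[intersect(names(raw),
                           setdiff(names(formals(task_config)), "task"))]
  cfg <- do.call(task_config, c(list(task = task), tc_args))
  win <- window_spec(raw$window$length_s %||% 30, raw$window$step_s %||% 1)
  list(task_config = cfg, window = win,
       channels = raw$channels,
       modalities = raw$modalities %||% if (task == "pulse") "ppg"
                                        else c("ppg", "acc"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
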
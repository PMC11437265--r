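modality_channels <- list(ppg = c("red", "ir"), acc = c("acc_y", "acc_z"))

#' Estimate pulse or respiratory rate from a multichannel recording
#'
#' Runs the full estimation framework over a recording: 30-s windows sliding
#' by 1 s are preprocessed per modality (pulse pipeline for PPG pulse
#' estimation; stream band-pass + per-window smoothing/derivative for
#' respiration), scored by the recursive artifact-aware dominance procedure,
#' fused across modalities, and tracked by the EWMA band estimator with
#' confidence gating. One output row is produced per window, timestamped at
#' the window end.
#'
#' Pulse estimation supports the PPG modality only (breathing motion, not the
#' pulse, is what the neck accelerometer resolves); respiratory estimation
#' accepts PPG, accelerometer, or their fusion.
#'
#' @param channels Named list of [signal_channel()]s (from
#'   [read_recording()] or the simulator). Pulse needs `red` + `ir`;
#'   respiratory needs `red` + `ir` and/or `acc_y` + `acc_z`.
#' @param task `"pulse"` or `"respiratory"`.
#' @param modalities Character subset of `c("ppg", "acc")`.
#' @param cfg A [task_config()] (default: the task's published defaults).
#' @param window A [window_spec()] (default 30 s / 1 s).
#' @return Object of class `rate_track`: list with `estimates` (data frame
#'   `t`, `rate_value`, `band_center`, `band_low`, `band_high`,
#'   `confident`), `cfg`, `window`, `task`, `modalities`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_recording("respiratory",
#'                           schedule = rate_schedule(c(12, 15), 60),
#'                           noise = noise_preset("clean"), seed = 1)
#' tr <- estimate_rates(sim$channels, "respiratory", c("ppg", "acc"))
#' summary(tr)
#' }
estimate_rates <- function(channels,
                           task = c("respiratory", "pulse"),
                           modalities = c("ppg", "acc"),
                           cfg = task_config(task),
                           window = window_spec()) {
  task <- match.arg(task)
  modalities <- match.arg(modalities, c("ppg", "acc"), several.ok = TRUE)
  if (task == "pulse" && !identical(modalities, "ppg"))
    stop("pulse estimation supports the 'ppg' modality only")
  if (cfg$task != task) stop("cfg was built for a different task")

  needed <- unlist(modality_channels[modalities])
  missing <- setdiff(needed, names(channels))
  if (length(missing))
    stop(sprintf("channel %s not found", paste(missing, collapse = ", ")))

  # cut per-channel windows; respiratory streams are band-passed first
  winset <- lapply(modalities, function(m) {
    chs <- channels[modality_channels[[m]]]
    if (task == "respiratory") chs <- lapply(chs, resp_prefilter)
    lapply(chs, sliding_windows, spec = window)
  })
  names(winset) <- modalities
  nwin <- min(vapply(winset, function(ws)
    min(vapply(ws, function(w) length(w$t), integer(1))), integer(1)))
  if (nwin == 0) stop("recording shorter than one analysis window")
  tend <- winset[[1]][[1]]$t[seq_len(nwin)]

  state <- ewma_state(cfg)
  rows <- vector("list", nwin)
  for (i in seq_len(nwin)) {
    ds <- dominance_scores()
    for (m in modalities) {
      ws <- winset[[m]]
      fs <- channels[[modality_channels[[m]][1]]]$fs
      seg <- if (task == "pulse") {
        preprocess_pulse_window(ws[[1]]$windows[[i]], ws[[2]]$windows[[i]],
                                fs_in = fs, t = tend[i])
      } else {
        preprocess_resp_window(ws[[1]]$windows[[i]], ws[[2]]$windows[[i]],
                               fs = fs, modality = m, t = tend[i])
      }
      ds_m <- get_dominance_scores(seg$samples, seg$fs, cfg)
      ds <- combine_modalities(ds, ds_m)
    }
    res <- estimator_step(ds, state, cfg, t = tend[i])
    state <- res$state
    rows[[i]] <- res$estimate
  }
  estimates <- do.call(rbind, rows)
  structure(list(estimates = estimates, cfg = cfg, window = window,
                 task = task, modalities = modalities),
            class = "rate_track")
}

#' @export
print.rate_track <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<rate_track> %s rate, modalities: %s\n", x$task,
              paste(x$modalities, collapse = "+")))
  cat(sprintf("  %d timesteps (%.0f-%.0f s), %.1f%% confident output\n",
              nrow(e), min(e$t), max(e$t), 100 * mean(e$confident)))
  invisible(x)
}

#' @export
summary.rate_track <- function(object, ...) {
  e <- object$estimates
  conf <- e[e$confident, , drop = FALSE]
  cat(sprintf("%s rate track (%s), %d windows\n", object$task,
              paste(object$modalities, collapse = "+"), nrow(e)))
  cat(sprintf("  confident band output: %.1f%% of timesteps\n",
              100 * mean(e$confident)))
  cat(sprintf("  rate-value output:     %.1f%% of timesteps\n",
              100 * mean(!is.na(e$rate_value))))
  if (nrow(conf)) {
    cat(sprintf("  band centers: median %g, range %g-%g %s\n",
                stats::median(conf$band_center), min(conf$band_center),
                max(conf$band_center), object$cfg$units))
  }
  invisible(object)
}

#' @export
as.data.frame.rate_track <- function(x, ...) x$estimates

#' Plot a rate track
#'
#' Band estimates are drawn as a shaded ribbon, point rate values as dots,
#' and an optional reference series as a line.
#'
#' @param x A `rate_track`.
#' @param reference Optional data frame with `time`, `rate`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rate_track <- function(x, reference = NULL, ...) {
  e <- x$estimates[x$estimates$confident, , drop = FALSE]
  ylim <- range(c(e$band_low, e$band_high, reference$rate), na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$estimates$t), ylim = ylim,
                 xlab = "time (s)",
                 ylab = sprintf("rate (%s)", x$cfg$units), ...)
  if (nrow(e)) {
    graphics::polygon(c(e$t, rev(e$t)), c(e$band_low, rev(e$band_high)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    ok <- !is.na(e$rate_value)
    graphics::points(e$t[ok], e$rate_value[ok], pch = 16, cex = 0.4,
                     col = "steelblue4")
  }
  if (!is.null(reference))
    graphics::lines(reference$time, reference$rate, col = "firebrick")
  invisible(x)
}
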
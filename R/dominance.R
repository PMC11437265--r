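#' Empty dominance-score map
#'
#' Dominance scores are a sparse map from integer rate to a positive
#' accumulated score; rates with zero score are absent.
#'
#' @return Object of class `dominance_scores` (named numeric vector).
#' @export
dominance_scores <- function() {
  structure(stats::setNames(numeric(0), character(0)),
            class = "dominance_scores")
}

ds_rates <- function(ds) as.integer(names(ds))

#' @export
print.dominance_scores <- function(x, ...) {
  if (!length(x)) { cat("<dominance_scores> empty\n"); return(invisible(x)) }
  o <- order(as.integer(names(x)))
  cat("<dominance_scores>",
      paste(sprintf("%s:%.3f", names(x)[o], unclass(x)[o]), collapse = " "),
      "\n")
  invisible(x)
}

#' Locate clean sub-segments around amplitude deviations
#'
#' Marks samples whose standardized amplitude deviates beyond
#' `[-dev_bound, dev_bound]` and returns the maximal deviation-free intervals
#' that are at least `min_subseg_s` seconds long. An empty result with no
#' deviating sample means "no dissection needed"; an empty result while
#' deviations exist means no flanking region is long enough to analyse.
#'
#' @param x Standardized samples.
#' @param fs Sampling rate in Hz.
#' @param cfg A [task_config()].
#' @return List of integer `c(start, end)` sample index pairs (inclusive),
#'   disjoint and ordered.
#' @export
find_clean_subsegments <- function(x, fs, cfg) {
  dev <- abs(x) > cfg$dev_bound
  if (!any(dev)) return(list())
  r <- rle(!dev)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= cfg$min_subseg_s * fs
  Map(c, starts[keep], ends[keep])
}

#' Aggregate a probability estimate into dominance scores
#'
#' Adds `prob / level` to the score of every rate whose probability is at
#' least `cfg$proba_floor` (0.1 by default: weaker components are
#' negligible). The recursion-level weight `1/level` discounts the reduced
#' spectral certainty of shorter sub-segments.
#'
#' @param ds A `dominance_scores` accumulator.
#' @param proba A `rate_probability` from [get_proba_estimations()].
#' @param level Recursion level (root = 1).
#' @param cfg A [task_config()].
#' @return Updated `dominance_scores`.
#' @export
update_ds <- function(ds, proba, level, cfg) {
  stopifnot(level >= 1)
  sel <- proba$probs >= cfg$proba_floor
  if (!any(sel)) return(ds)
  add <- stats::setNames(proba$probs[sel] / level,
                         as.character(proba$rates[sel]))
  merge_scores(ds, add)
}

merge_scores <- function(ds, add) {
  out <- unclass(ds)
  common <- intersect(names(out), names(add))
  out[common] <- out[common] + add[common]
  new <- setdiff(names(add), names(out))
  out <- c(out, add[new])
  structure(out, class = "dominance_scores")
}

#' Dominance scores of a segment via recursive dissection
#'
#' Scores a standardized segment by its softmax spectral probabilities,
#' recursively dissecting it around intra-window artifacts: when samples
#' deviate beyond the standardized bound, the deviation-free flanks (>= 5 s)
#' are re-standardized and scored at the next recursion level instead of the
#' contaminated whole; their contributions are weighted by `1/level`.
#' Recursion stops at depth `cfg$max_depth` (20) or when no flank reaches
#' `cfg$min_subseg_s` (5 s), in which case the segment contributes its own
#' estimate at the current level.
#'
#' @param x Standardized segment samples.
#' @param fs Sampling rate in Hz.
#' @param cfg A [task_config()].
#' @param level Starting recursion level (root = 1).
#' @param trace Optional environment; when supplied, each analysed leaf and
#'   recursion call is appended to `trace$calls` as `c(level, n_samples)`
#'   (used for instrumentation).
#' @return A `dominance_scores` map.
#' @export
get_dominance_scores <- function(x, fs, cfg, level = 1, trace = NULL) {
  if (!is.null(trace))
    trace$calls <- c(trace$calls, list(c(level = level, n = length(x))))
  intervals <- find_clean_subsegments(x, fs, cfg)
  if (level >= cfg$max_depth || length(intervals) == 0) {
    return(update_ds(dominance_scores(), get_proba_estimations(x, fs, cfg),
                     level, cfg))
  }
  ds <- dominance_scores()
  for (iv in intervals) {
    sub <- standardize(x[iv[1]:iv[2]])
    ds <- merge_scores(ds, get_dominance_scores(sub, fs, cfg, level + 1,
                                                trace))
  }
  ds
}

#' Combine dominance scores across modalities
#'
#' Rate-wise sum of two maps inferred independently (e.g. PPG- and
#' accelerometer-derived respiratory scores for the same timestep).
#'
#' @param ds_a,ds_b `dominance_scores` from the same timestep and task.
#' @return Combined `dominance_scores`.
#' @export
combine_modalities <- function(ds_a, ds_b) merge_scores(ds_a, unclass(ds_b))
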
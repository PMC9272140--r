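#' Session pupil baseline statistics
#'
#' Pools the valid pupil samples of all pre-stimulus central-fixation
#' segments of a session and returns their mean and SD (n-1 convention).
#' Blink-masked samples (zero pupil or invalid flag) are excluded. A zero-SD
#' baseline is flagged degenerate: z-scores are undefined against it.
#'
#' @param baselines a data frame of baseline samples (columns `pupil_au`,
#'   `valid`), or a `trial_segments` object whose `baseline` elements are
#'   pooled.
#' @return object of class `pupil_baseline`: list with `mean_au`, `sd_au`,
#'   `n`, `degenerate`.
#' @export
baseline_stats <- function(baselines) {
  if (inherits(baselines, "trial_segments"))
    baselines <- do.call(rbind, lapply(baselines, `[[`, "baseline"))
  keep <- baselines$valid & baselines$pupil_au > 0
  p <- baselines$pupil_au[keep]
  if (length(p) == 0) stop_("no valid baseline pupil samples")
  sd_au <- if (length(p) > 1) stats::sd(p) else 0
  structure(list(mean_au = mean(p), sd_au = sd_au, n = length(p),
                 degenerate = sd_au == 0),
            class = "pupil_baseline")
}

#' @export
print.pupil_baseline <- function(x, ...) {
  cat(sprintf("<pupil_baseline> mean %.2f au, sd %.2f au, n = %d%s\n",
              x$mean_au, x$sd_au, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mean pupil size of a fixation
#'
#' Arithmetic mean of the valid, non-blink pupil samples within
#' `[onset_ms, offset_ms)`. Missing when the fixation has no usable sample.
#'
#' @param fixation one-row fixation event (`onset_ms`, `offset_ms`).
#' @param series the trial's sample series.
#' @param blinks optional blink intervals to exclude (from
#'   [detect_blinks()]).
#' @return mean pupil in arbitrary units, or `NA`.
#' @export
fixation_pupil <- function(fixation, series, blinks = NULL) {
  inwin <- series$t_ms >= fixation$onset_ms & series$t_ms < fixation$offset_ms
  ok <- inwin & series$valid & series$pupil_au > 0
  if (!is.null(blinks))
    for (b in seq_len(nrow(blinks)))
      ok <- ok & !(series$t_ms >= blinks$onset_ms[b] &
                   series$t_ms < blinks$offset_ms[b])
  if (!any(ok)) return(NA_real_)
  mean(series$pupil_au[ok])
}

#' z-score pupil sizes against a session baseline
#'
#' `z = (pupil_au - mean_au) / sd_au` with the session's pooled pre-stimulus
#' baseline. Errors on a degenerate (zero-SD) baseline.
#'
#' @param pupil_au pupil values (au), vectorized; `NA` passes through.
#' @param baseline a [baseline_stats()] result.
#' @return numeric vector of z-scores.
#' @export
zscore_pupil <- function(pupil_au, baseline) {
  stopifnot(inherits(baseline, "pupil_baseline"))
  if (baseline$degenerate)
    stop_("degenerate baseline (sd = 0): z-scores are undefined")
  (pupil_au - baseline$mean_au) / baseline$sd_au
}
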
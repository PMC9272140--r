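#' Label fixations with AOI and facial ROI
#'
#' Adds `aoi` (`face`/`agr`/`off`) by centroid-in-window and, for face
#' fixations, `roi` via [assign_roi()].
#'
#' @param fixations fixation data frame (from [detect_fixations()]).
#' @param layout one-row trial layout.
#' @param map optional [roi_map()] for the trial's face window; the default
#'   map is built from the layout when `NULL`.
#' @return `fixations` with `aoi` and `roi` columns appended.
#' @export
label_fixations <- function(fixations, layout, map = NULL) {
  if (nrow(fixations) == 0) {
    fixations$aoi <- character(0); fixations$roi <- character(0)
    return(fixations)
  }
  if (is.null(map))
    map <- default_roi_map(c(layout$face_cx, layout$face_cy,
                             layout$face_w, layout$face_h))
  fixations$aoi <- assign_aoi(fixations$x_deg, fixations$y_deg, layout)
  fixations$roi <- NA_character_
  for (i in which(fixations$aoi == "face"))
    fixations$roi[i] <- assign_roi(fixations$x_deg[i], fixations$y_deg[i], map)
  fixations
}

#' First-gaze label of a trial
#'
#' The AOI of the first fixation after display onset whose centroid has left
#' the central fixation window and lands in either image window. Off-image
#' landings are skipped (the measure is the face-vs-AGR dichotomy);
#' `"none"` if gaze never reaches an image window.
#'
#' @param fixations time-ordered, AOI-labelled fixations of one trial's
#'   display period.
#' @param layout one-row trial layout (supplies the central fixation
#'   window).
#' @return `"face"`, `"agr"` or `"none"`.
#' @export
first_gaze <- function(fixations, layout) {
  if (nrow(fixations) == 0) return("none")
  fix_win <- c(layout$fix_cx, layout$fix_cy, layout$fix_w, layout$fix_h)
  for (i in order(fixations$onset_ms)) {
    if (in_rect(fixations$x_deg[i], fixations$y_deg[i], fix_win)) next
    if (fixations$aoi[i] %in% c("face", "agr")) return(fixations$aoi[i])
  }
  "none"
}

#' Per-trial viewing-preference metrics
#'
#' Computes the trial's headline numbers from its AOI-labelled fixations:
#' in-window fixation counts and dwell per image, the AGR preference
#' `pagr = n_agr / (n_agr + n_face)` (missing when no in-window fixation
#' exists), the first-gaze label, mean fixation lengths, and per-ROI
#' fixation counts. Off-window fixations are tallied (`n_fix_off`) but enter
#' no headline metric.
#'
#' @param fixations AOI/ROI-labelled fixations of a single trial.
#' @param layout the trial's one-row layout (condition labels are copied
#'   into the result).
#' @return one-row data frame of class `trial_metrics`.
#' @export
compute_trial_metrics <- function(fixations, layout) {
  if ("trial" %in% names(fixations) && length(unique(fixations$trial)) > 1)
    stop_("fixations from mixed trials: %s",
          paste(unique(fixations$trial), collapse = ", "))
  if (!"aoi" %in% names(fixations))
    stop_("fixations must carry AOI labels; run label_fixations() first")
  face <- fixations[fixations$aoi == "face", , drop = FALSE]
  agr <- fixations[fixations$aoi == "agr", , drop = FALSE]
  n_face <- nrow(face); n_agr <- nrow(agr)
  total <- n_face + n_agr
  dwell_face <- sum(face$duration_ms)
  dwell_agr <- sum(agr$duration_ms)
  roi_counts <- vapply(c("forehead", "eyes", "nose", "mouth", "other"),
                       function(r) sum(face$roi == r, na.rm = TRUE), integer(1))
  out <- data.frame(
    session = layout$session, trial = layout$trial,
    n_fix_face = n_face, n_fix_agr = n_agr, total_fix = total,
    dwell_face_ms = dwell_face, dwell_agr_ms = dwell_agr,
    pagr = if (total > 0) n_agr / total else NA_real_,
    first_gaze = first_gaze(fixations, layout),
    mean_fix_len_ms = if (total > 0) (dwell_face + dwell_agr) / total else NA_real_,
    mean_fix_len_face_ms = if (n_face > 0) dwell_face / n_face else NA_real_,
    mean_fix_len_agr_ms = if (n_agr > 0) dwell_agr / n_agr else NA_real_,
    n_fix_off = sum(fixations$aoi == "off"),
    roi_forehead = roi_counts[["forehead"]], roi_eyes = roi_counts[["eyes"]],
    roi_nose = roi_counts[["nose"]], roi_mouth = roi_counts[["mouth"]],
    roi_other = roi_counts[["other"]],
    treatment = layout$treatment, image_sex = layout$image_sex,
    age_class = layout$age_class, familiarity = layout$familiarity,
    face_side = layout$face_side, monkey_id = layout$monkey_id,
    stringsAsFactors = FALSE)
  class(out) <- c("trial_metrics", "data.frame")
  out
}

#' Aggregate trial metrics into condition summaries
#'
#' Per grouping cell: mean, standard error (`sd/sqrt(n)`, missing for
#' `n < 2`) and n of each numeric metric over non-missing trials, plus the
#' first-gaze AGR proportion with its binomial standard error. Cells with no
#' trials are omitted; trials with missing `pagr` are excluded from the
#' `pagr` rows only.
#'
#' @param metrics stacked `trial_metrics` rows.
#' @param keys character vector of grouping columns (subset of the condition
#'   labels, e.g. `c("treatment", "image_sex")`).
#' @param metrics_cols numeric metric columns to summarize.
#' @return long-format data frame: grouping keys, `metric`, `mean`, `se`,
#'   `n`.
#' @export
aggregate_metrics <- function(metrics, keys,
                              metrics_cols = c("pagr", "total_fix", "n_fix_face",
                                               "n_fix_agr", "dwell_face_ms",
                                               "dwell_agr_ms", "mean_fix_len_ms")) {
  bad <- setdiff(keys, names(metrics))
  if (length(bad)) stop_("unknown grouping key(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(metrics_cols, names(metrics))
  if (length(bad)) stop_("unknown metric column(s): %s", paste(bad, collapse = ", "))
  cells <- split(metrics, interaction(metrics[keys], drop = TRUE, sep = "\r"))
  rows <- lapply(cells, function(cell) {
    keyvals <- cell[1, keys, drop = FALSE]
    per_metric <- lapply(metrics_cols, function(m) {
      v <- cell[[m]]
      v <- v[!is.na(v)]
      data.frame(keyvals, metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 se = se_mean(v), n = length(v),
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    fg <- cell$first_gaze[cell$first_gaze %in% c("face", "agr")]
    p <- if (length(fg)) mean(fg == "agr") else NA_real_
    fg_row <- data.frame(keyvals, metric = "first_gaze_agr",
                         mean = p,
                         se = if (length(fg) >= 2)
                           sqrt(p * (1 - p) / length(fg)) else NA_real_,
                         n = length(fg),
                         row.names = NULL, stringsAsFactors = FALSE)
    do.call(rbind, c(per_metric, list(fg_row)))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage of face fixations per facial ROI
#'
#' `100 * count_ROI / count_total` over fixations already labelled
#' `aoi == "face"`; percentages sum to 100 exactly. All-missing when the
#' input is empty.
#'
#' @param fixations ROI-labelled face fixations.
#' @return named numeric vector over
#'   `forehead`, `eyes`, `nose`, `mouth`, `other`.
#' @export
roi_fixation_percentages <- function(fixations) {
  rois <- c("forehead", "eyes", "nose", "mouth", "other")
  if (nrow(fixations) == 0)
    return(stats::setNames(rep(NA_real_, 5), rois))
  if (any(fixations$aoi != "face"))
    stop_("roi_fixation_percentages expects face fixations only")
  counts <- vapply(rois, function(r) sum(fixations$roi == r), numeric(1))
  100 * counts / sum(counts)
}
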
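# Sample logs are plain TSV with the fixed header
#   session  trial  t_ms  x_deg  y_deg  pupil_au  valid
# Timestamps are integer milliseconds, strictly increasing within a trial;
# invalid samples may carry missing x/y. Coordinates are written at 1e-4 deg
# and pupil at 1e-3 au resolution (the canonical form for round-trips).

SAMPLE_COLUMNS <- c("session", "trial", "t_ms", "x_deg", "y_deg", "pupil_au", "valid")

# Round a log to the canonical on-disk resolution.
canonicalize_samples <- function(log) {
  log$t_ms <- as.numeric(log$t_ms)
  log$x_deg <- round(as.numeric(log$x_deg), 4)
  log$y_deg <- round(as.numeric(log$y_deg), 4)
  log$pupil_au <- round(as.numeric(log$pupil_au), 3)
  log$valid <- as.logical(log$valid)
  log$session <- as.character(log$session)
  rownames(log) <- NULL
  log[, SAMPLE_COLUMNS]
}

check_sample_log <- function(log) {
  miss <- setdiff(SAMPLE_COLUMNS, names(log))
  if (length(miss)) stop_("sample log is missing column(s): %s",
                          paste(miss, collapse = ", "))
  extra <- setdiff(names(log), SAMPLE_COLUMNS)
  if (length(extra)) stop_("unknown column(s) in sample log: %s",
                           paste(extra, collapse = ", "))
  if (any(log$pupil_au < 0, na.rm = TRUE)) stop_("pupil_au must be >= 0")
  key <- paste(log$session, log$trial)
  for (k in unique(key)) {
    t <- log$t_ms[key == k]
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop_("non-monotone timestamps within trial %s: first offence at row %d (t_ms = %s)",
            k, bad[1] + 1L, format(t[bad[1] + 1L]))
  }
  invisible(log)
}

#' Read and write gaze sample logs (TSV)
#'
#' The on-disk format is tab-separated with the fixed header
#' `session trial t_ms x_deg y_deg pupil_au valid`. Reading validates the
#' schema and strict within-trial timestamp monotonicity; writing emits the
#' canonical resolution (1e-4 deg, 1e-3 au), so `read_samples(write_samples(x))`
#' is the identity on canonical-form logs.
#'
#' @param path file path.
#' @return `read_samples()`: data frame with the seven schema columns.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_("sample log not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!identical(strsplit(first, "\t")[[1]], SAMPLE_COLUMNS))
    stop_("sample log header does not match schema: %s", first)
  log <- utils::read.delim(path, colClasses = c(
    session = "character", trial = "integer", t_ms = "numeric",
    x_deg = "numeric", y_deg = "numeric", pupil_au = "numeric",
    valid = "integer"))
  log$valid <- log$valid == 1L
  if (nrow(log)) check_sample_log(log)
  canonicalize_samples(log)
}

#' @rdname read_samples
#' @param log sample-log data frame.
#' @export
write_samples <- function(log, path) {
  log <- canonicalize_samples(log)
  check_sample_log(log)
  out <- log
  out$valid <- as.integer(out$valid)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Segment a continuous recording into trials
#'
#' Clips each trial's samples to its display period `[onset, offset)` and
#' keeps the pre-stimulus central-fixation segment (all of the trial's
#' samples before onset) separately for pupil baselining; any post-display
#' samples are returned as the remainder. Trials whose display period holds
#' fewer than 50% valid samples of the expected count are flagged with a
#' warning.
#'
#' @param log sample-log data frame.
#' @param layouts trial-layout data frame (one row per trial with `session`,
#'   `trial`, `onset_ms`, `offset_ms` and window geometry).
#' @return object of class `trial_segments`: a list with one element per
#'   layout row, each holding `display`, `baseline`, `remainder` data frames,
#'   the `layout` row and a `flagged` logical.
#' @export
segment_trials <- function(log, layouts) {
  check_sample_log(log)
  key <- paste(log$session, log$trial)
  out <- vector("list", nrow(layouts))
  for (i in seq_len(nrow(layouts))) {
    ly <- layouts[i, , drop = FALSE]
    idx <- key == paste(ly$session, ly$trial)
    if (!any(idx))
      stop_("trial %s/%s has no samples in the log", ly$session, ly$trial)
    tr <- log[idx, , drop = FALSE]
    if (ly$onset_ms >= max(tr$t_ms))
      stop_("trial %s/%s: display onset %g lies beyond the trial's samples",
            ly$session, ly$trial, ly$onset_ms)
    disp <- tr[tr$t_ms >= ly$onset_ms & tr$t_ms < ly$offset_ms, , drop = FALSE]
    base <- tr[tr$t_ms < ly$onset_ms, , drop = FALSE]
    rest <- tr[tr$t_ms >= ly$offset_ms, , drop = FALSE]
    dt <- if (nrow(tr) > 1) stats::median(diff(tr$t_ms)) else 1
    expected <- (ly$offset_ms - ly$onset_ms) / dt
    flagged <- sum(disp$valid) < 0.5 * expected
    if (flagged)
      warn_("trial %s/%s flagged: %d valid display samples of %g expected",
            ly$session, ly$trial, sum(disp$valid), expected)
    out[[i]] <- list(display = disp, baseline = base, remainder = rest,
                     layout = ly, flagged = flagged)
  }
  names(out) <- paste(layouts$session, layouts$trial, sep = "/")
  structure(out, class = "trial_segments")
}

#' @export
print.trial_segments <- function(x, ...) {
  cat(sprintf("<trial_segments> %d trials (%d flagged)\n", length(x),
              sum(vapply(x, `[[`, logical(1), "flagged"))))
  invisible(x)
}

#' Read / write trial layout tables
#'
#' Layout tables are CSV, one row per trial, windows as centre/width/height
#' in degrees.
#'
#' @param layouts layout data frame; `path` file path.
#' @export
write_layouts <- function(layouts, path) {
  utils::write.csv(layouts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layouts
#' @export
read_layouts <- function(path) {
  if (!file.exists(path)) stop_("layout file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
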
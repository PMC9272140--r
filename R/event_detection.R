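#' Detector parameters
#'
#' Parameters of the dispersion-threshold (I-DT) fixation detector. The
#' dispersion metric is the classic I-DT one: (max-min of x) + (max-min of
#' y) within the candidate window.
#'
#' @param dispersion_deg maximum spatial spread within a fixation (deg).
#' @param min_duration_ms minimum fixation duration (ms).
#' @param blink_pad_ms padding added to each side of a blink interval.
#' @param merge_gap_ms maximum gap between consecutive fixations eligible
#'   for merging (merged only if the combined dispersion stays within
#'   threshold).
#' @return object of class `detector_params`.
#' @export
detector_params <- function(dispersion_deg = 1.0, min_duration_ms = 60,
                            blink_pad_ms = 50, merge_gap_ms = 20) {
  vals <- c(dispersion_deg, min_duration_ms, blink_pad_ms, merge_gap_ms)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_("all detector parameters must be positive")
  structure(list(dispersion_deg = dispersion_deg,
                 min_duration_ms = min_duration_ms,
                 blink_pad_ms = blink_pad_ms, merge_gap_ms = merge_gap_ms),
            class = "detector_params")
}

#' Detect blink intervals
#'
#' Blinks are maximal runs of samples with zero pupil or an invalid flag,
#' extended by `blink_pad_ms` on both sides (eye-tracker pupil estimates are
#' unreliable around lid closure) and clipped to the series extent.
#' Overlapping padded intervals are merged. Samples inside the returned
#' intervals are excluded from fixation detection and pupil averaging.
#'
#' @param series sample data frame (columns `t_ms`, `pupil_au`, `valid`).
#' @param params a [detector_params()].
#' @return data frame with `onset_ms`, `offset_ms` (half-open intervals),
#'   empty when the series is clean.
#' @export
detect_blinks <- function(series, params = detector_params()) {
  if (nrow(series) == 0)
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  stopifnot(!is.unsorted(series$t_ms))
  bad <- series$pupil_au == 0 | !series$valid
  if (!any(bad))
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  dt <- if (nrow(series) > 1) stats::median(diff(series$t_ms)) else 1
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  on <- series$t_ms[starts[runs]] - params$blink_pad_ms
  off <- series$t_ms[ends[runs]] + dt + params$blink_pad_ms
  lo <- series$t_ms[1]; hi <- series$t_ms[nrow(series)] + dt
  on <- pmax(on, lo); off <- pmin(off, hi)
  # merge overlapping / touching padded intervals
  merged_on <- on[1]; merged_off <- off[1]
  if (length(on) > 1) {
    for (i in 2:length(on)) {
      last <- length(merged_off)
      if (on[i] <= merged_off[last]) {
        merged_off[last] <- max(merged_off[last], off[i])
      } else {
        merged_on <- c(merged_on, on[i]); merged_off <- c(merged_off, off[i])
      }
    }
  }
  data.frame(onset_ms = merged_on, offset_ms = merged_off)
}

# Core I-DT pass over one clean (blink-free) segment. Greedy maximal-window
# growth with incremental bounding-box updates: at position i, extend j while
# the dispersion (x-range + y-range) stays within threshold; emit the window
# as a fixation if it spans at least min_duration, else advance one sample.
idt_core <- function(t, x, y, dispersion, min_dur, dt) {
  n <- length(t)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n) {
    xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
    j <- i
    while (j < n) {
      xn <- x[j + 1L]; yn <- y[j + 1L]
      nxmin <- if (xn < xmin) xn else xmin
      nxmax <- if (xn > xmax) xn else xmax
      nymin <- if (yn < ymin) yn else ymin
      nymax <- if (yn > ymax) yn else ymax
      if ((nxmax - nxmin) + (nymax - nymin) > dispersion) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    if (t[j] - t[i] + dt >= min_dur) {
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(starts = starts, ends = ends)
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' Grows a sample window while its dispersion — (max-min of x) + (max-min of
#' y) — stays within `dispersion_deg`, and emits a fixation when the maximal
#' window spans at least `min_duration_ms`. Blink intervals are removed
#' first and always terminate the current window (fixations never span a
#' blink). Consecutive fixations separated by less than `merge_gap_ms`
#' whose combined dispersion stays within threshold are merged. Centroids
#' and mean pupil are arithmetic means over the constituent samples.
#'
#' @param series sample data frame (`t_ms`, `x_deg`, `y_deg`, `pupil_au`,
#'   `valid`), time-sorted.
#' @param params a [detector_params()].
#' @param blinks optional precomputed blink table (from [detect_blinks()]);
#'   computed internally when `NULL`.
#' @param merge set `FALSE` to skip the merge pass (used by oracle tests).
#' @return data frame of fixation events: `onset_ms`, `offset_ms`,
#'   `duration_ms`, centroid `x_deg`/`y_deg`, `pupil_au`, `n_samples`.
#' @export
detect_fixations <- function(series, params = detector_params(), blinks = NULL,
                             merge = TRUE) {
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), x_deg = numeric(0),
                      y_deg = numeric(0), pupil_au = numeric(0),
                      n_samples = integer(0))
  if (is.null(series) || nrow(series) == 0) return(empty)
  stopifnot(!is.unsorted(series$t_ms))
  if (is.null(blinks)) blinks <- detect_blinks(series, params)
  dt <- if (nrow(series) > 1) stats::median(diff(series$t_ms)) else 1

  masked <- rep(FALSE, nrow(series))
  for (b in seq_len(nrow(blinks)))
    masked <- masked | (series$t_ms >= blinks$onset_ms[b] &
                        series$t_ms < blinks$offset_ms[b])
  masked <- masked | is.na(series$x_deg) | is.na(series$y_deg) | !series$valid
  keep <- which(!masked)
  if (!length(keep)) return(empty)

  # segment ids: a new segment starts after every masked gap
  seg_id <- cumsum(c(1, diff(keep) > 1))
  out <- vector("list", max(seg_id))
  for (s in unique(seg_id)) {
    idx <- keep[seg_id == s]
    t <- series$t_ms[idx]; x <- series$x_deg[idx]; y <- series$y_deg[idx]
    res <- idt_core(t, x, y, params$dispersion_deg, params$min_duration_ms, dt)
    if (!length(res$starts)) next
    windows <- Map(function(a, b) idx[a:b], res$starts, res$ends)
    if (merge && length(windows) > 1) {
      merged <- list(windows[[1]])
      for (w in windows[-1]) {
        last <- merged[[length(merged)]]
        gap <- series$t_ms[w[1]] - (series$t_ms[last[length(last)]] + dt)
        if (gap < params$merge_gap_ms) {
          comb <- c(last, w)
          disp <- diff(range(series$x_deg[comb])) + diff(range(series$y_deg[comb]))
          if (disp <= params$dispersion_deg) {
            merged[[length(merged)]] <- comb
            next
          }
        }
        merged <- c(merged, list(w))
      }
      windows <- merged
    }
    out[[s]] <- do.call(rbind, lapply(windows, function(w) {
      data.frame(onset_ms = series$t_ms[w[1]],
                 offset_ms = series$t_ms[w[length(w)]] + dt,
                 duration_ms = series$t_ms[w[length(w)]] + dt - series$t_ms[w[1]],
                 x_deg = mean(series$x_deg[w]), y_deg = mean(series$y_deg[w]),
                 pupil_au = mean(series$pupil_au[w]),
                 n_samples = length(w))
    }))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Derive saccades from a fixation list
#'
#' One saccade per adjacent fixation pair, spanning the inter-fixation gap;
#' nothing is emitted before the first or after the last fixation.
#'
#' @param fixations fixation data frame from [detect_fixations()],
#'   time-ordered.
#' @return data frame with `onset_ms`, `offset_ms`, `duration_ms`, start and
#'   end positions.
#' @export
derive_saccades <- function(fixations) {
  if (nrow(fixations) < 2)
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), x_start = numeric(0),
                      y_start = numeric(0), x_end = numeric(0),
                      y_end = numeric(0)))
  k <- nrow(fixations)
  on <- fixations$offset_ms[-k]
  off <- fixations$onset_ms[-1]
  if (any(off < on))
    stop_("overlapping fixations at index %d: upstream invariant breach",
          which(off < on)[1])
  data.frame(onset_ms = on, offset_ms = off, duration_ms = off - on,
             x_start = fixations$x_deg[-k], y_start = fixations$y_deg[-k],
             x_end = fixations$x_deg[-1], y_end = fixations$y_deg[-1])
}
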
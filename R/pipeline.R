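with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Analyze one session of samples
#'
#' Runs the per-session analysis chain: trial segmentation, blink masking,
#' I-DT fixation detection on the display period, AOI/ROI labelling,
#' per-trial metrics, and baseline-z-scored fixation pupil sizes.
#'
#' @param samples sample-log data frame (or a `gaze_session`, whose samples
#'   and layouts are used directly).
#' @param layouts trial-layout data frame (ignored when `samples` is a
#'   `gaze_session`).
#' @param detector a [detector_params()].
#' @return list with `fixations` (labelled events incl. `pupil_z`),
#'   `metrics` (one row per trial), `baseline` (a `pupil_baseline`) and
#'   `flagged` (trial flags from segmentation).
#' @export
analyze_session <- function(samples, layouts = NULL,
                            detector = detector_params()) {
  if (inherits(samples, "gaze_session")) {
    layouts <- samples$layouts
    samples <- samples$samples
  }
  if (is.null(layouts)) stop_("layouts are required")
  segs <- with_stage("segment_trials", segment_trials(samples, layouts))

  base_rows <- vector("list", length(segs))
  fix_rows <- vector("list", length(segs))
  met_rows <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    ly <- seg$layout
    trial_series <- rbind(seg$baseline, seg$display, seg$remainder)
    blinks <- with_stage("detect_blinks", detect_blinks(trial_series, detector))
    bl <- seg$baseline
    if (nrow(blinks) && nrow(bl)) {
      drop <- rep(FALSE, nrow(bl))
      for (b in seq_len(nrow(blinks)))
        drop <- drop | (bl$t_ms >= blinks$onset_ms[b] &
                        bl$t_ms < blinks$offset_ms[b])
      bl <- bl[!drop, , drop = FALSE]
    }
    base_rows[[i]] <- bl
    fx <- with_stage(sprintf("detect_fixations (trial %s)", ly$trial),
                     detect_fixations(seg$display, detector, blinks = blinks))
    fx <- with_stage("label_fixations", label_fixations(fx, ly))
    if (nrow(fx)) {
      fx$session <- ly$session; fx$trial <- ly$trial
      fx$treatment <- ly$treatment; fx$image_sex <- ly$image_sex
      fx$age_class <- ly$age_class; fx$familiarity <- ly$familiarity
      fx$monkey_id <- ly$monkey_id
    }
    fix_rows[[i]] <- fx
    met_rows[[i]] <- with_stage(sprintf("compute_trial_metrics (trial %s)", ly$trial),
                                compute_trial_metrics(fx, ly))
  }
  baseline <- with_stage("baseline_stats",
                         baseline_stats(do.call(rbind, base_rows)))
  fixations <- do.call(rbind, fix_rows[vapply(fix_rows, nrow, 1L) > 0])
  if (is.null(fixations)) fixations <- fix_rows[[1]]
  if (nrow(fixations))
    fixations$pupil_z <- zscore_pupil(fixations$pupil_au, baseline)
  metrics <- do.call(rbind, met_rows)
  list(fixations = fixations, metrics = metrics, baseline = baseline,
       flagged = vapply(segs, `[[`, logical(1), "flagged"))
}

#' Pipeline configuration
#'
#' Assembles everything [run_pipeline()] needs: the stimulus catalogue, the
#' session design (subject x treatment x replicate), the generator and
#' detector parameters, aggregation keys, heat-map settings and the root
#' seed. Unknown fields in a config file are errors (fail-fast).
#'
#' @param catalogue a `gaze_catalogue`, or a path to a catalogue JSON, or
#'   `"female"`/`"male"` for the built-in sets.
#' @param sessions data frame with columns `subject` and `treatment` (one
#'   row per session); default: subject M1, 3 sessions per treatment.
#' @param generator a [gaze_config()]; its seed is overridden by `seed`.
#' @param detector a [detector_params()].
#' @param group_keys grouping columns for condition summaries.
#' @param heatmap_bins,heatmap_sigma heat-map grid size and smoothing SD
#'   (bins).
#' @param seed root seed for all randomness.
#' @param out_dir optional output directory; when set, every table is
#'   written as CSV plus a provenance JSON (config hash + seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(catalogue = "female",
                            sessions = NULL,
                            generator = gaze_config(),
                            detector = detector_params(),
                            group_keys = c("treatment", "image_sex"),
                            heatmap_bins = 50,
                            heatmap_sigma = 1,
                            seed = 1,
                            out_dir = NULL) {
  if (is.character(catalogue) && length(catalogue) == 1) {
    catalogue <- if (catalogue %in% c("female", "male"))
      default_catalogue(catalogue) else load_catalogue(catalogue)
  }
  stopifnot(inherits(catalogue, "gaze_catalogue"),
            inherits(generator, "gaze_config"),
            inherits(detector, "detector_params"))
  if (is.null(sessions))
    sessions <- data.frame(subject = "M1",
                           treatment = rep(c("SL", "OT", "TE"), each = 3),
                           stringsAsFactors = FALSE)
  if (!all(c("subject", "treatment") %in% names(sessions)))
    stop_("sessions needs 'subject' and 'treatment' columns")
  if (!all(sessions$treatment %in% c("SL", "OT", "TE")))
    stop_("treatments must be SL, OT or TE")
  structure(list(catalogue = catalogue, sessions = sessions,
                 generator = generator, detector = detector,
                 group_keys = group_keys, heatmap_bins = heatmap_bins,
                 heatmap_sigma = heatmap_sigma, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' Scalar fields map onto [pipeline_config()], [gaze_config()] and
#' [detector_params()] arguments under the `generator:` and `detector:`
#' keys. Unknown keys raise an error.
#'
#' @param path config file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known_top <- c("catalogue", "sessions", "generator", "detector",
                 "group_keys", "heatmap_bins", "heatmap_sigma", "seed", "out_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) stop_("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  gen_args <- raw$generator %||% list()
  bad <- setdiff(names(gen_args), names(formals(gaze_config)))
  if (length(bad)) stop_("unknown generator key(s): %s", paste(bad, collapse = ", "))
  det_args <- raw$detector %||% list()
  bad <- setdiff(names(det_args), names(formals(detector_params)))
  if (length(bad)) stop_("unknown detector key(s): %s", paste(bad, collapse = ", "))
  sessions <- if (!is.null(raw$sessions)) as.data.frame(raw$sessions) else NULL
  pipeline_config(catalogue = raw$catalogue %||% "female",
                  sessions = sessions,
                  generator = do.call(gaze_config, gen_args),
                  detector = do.call(detector_params, det_args),
                  group_keys = raw$group_keys %||% c("treatment", "image_sex"),
                  heatmap_bins = raw$heatmap_bins %||% 50,
                  heatmap_sigma = raw$heatmap_sigma %||% 1,
                  seed = raw$seed %||% 1,
                  out_dir = raw$out_dir)
}

#' Run the full gaze-preference pipeline
#'
#' Orchestrates catalogue, session plans, synthetic-gaze simulation, blink
#' and fixation detection, AOI/ROI mapping, per-trial metrics, pupil
#' z-scoring, pooled heat maps and the statistical report, deterministically
#' for a given (config, seed). Session seeds are derived from the root seed
#' by counter.
#'
#' @param config a [pipeline_config()].
#' @return object of class `gaze_analysis`: list with `metrics`,
#'   `fixations`, `summaries`, `roi_percentages`, `pupil_summary`,
#'   `heatmaps`, `stats`, `baselines`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- config$generator
  all_fix <- list(); all_met <- list(); baselines <- list()
  hm_face <- NULL; hm_agr <- NULL
  win <- c(0, 0, gen$window_size_deg, gen$window_size_deg)
  for (i in seq_len(nrow(config$sessions))) {
    srow <- config$sessions[i, ]
    plan <- with_stage("build_session_plan",
      build_session_plan(config$catalogue, srow$subject, srow$treatment,
                         seed = derive_seed(config$seed, 9000 + i),
                         session_id = sprintf("S%02d_%s_%s", i, srow$subject,
                                              srow$treatment)))
    gen_i <- gen
    gen_i$seed <- derive_seed(config$seed, i)
    sess <- with_stage("simulate_session",
                       simulate_session(plan, gen_i, config$catalogue))
    res <- analyze_session(sess, detector = config$detector)
    res$metrics$subject <- srow$subject
    if (nrow(res$fixations)) res$fixations$subject <- srow$subject
    all_fix[[i]] <- res$fixations
    all_met[[i]] <- res$metrics
    baselines[[plan$session_id]] <- res$baseline
    # pooled heat maps in window-centred coordinates
    hm <- with_stage("gaze_heatmap",
                     session_heatmap_counts(sess, config$heatmap_bins))
    hm_face <- if (is.null(hm_face)) hm$face else hm_face + hm$face
    hm_agr <- if (is.null(hm_agr)) hm$agr else hm_agr + hm$agr
  }
  fixations <- do.call(rbind, all_fix)
  metrics <- do.call(rbind, all_met)
  summaries <- with_stage("aggregate",
                          aggregate_metrics(metrics, config$group_keys))
  roi_pct <- with_stage("roi_percentages", roi_percent_table(fixations, config))
  pupil <- with_stage("pupil_summary", pupil_summary_table(fixations, config))
  stats_report <- with_stage("stats_battery", pipeline_stats(metrics))
  heatmaps <- list(
    face = heatmap_from_counts(hm_face, win, config$heatmap_sigma),
    agr = heatmap_from_counts(hm_agr, win, config$heatmap_sigma))
  out <- structure(
    list(metrics = metrics, fixations = fixations, summaries = summaries,
         roi_percentages = roi_pct, pupil_summary = pupil,
         heatmaps = heatmaps, stats = stats_report, baselines = baselines,
         config = config),
    class = "gaze_analysis")
  if (!is.null(config$out_dir)) write_bundle(out, config$out_dir)
  out
}

# Per-session heat-map counts per image type, in window-centred coordinates.
session_heatmap_counts <- function(sess, n_bins) {
  gen <- sess$config
  win <- c(0, 0, gen$window_size_deg, gen$window_size_deg)
  face <- matrix(0L, n_bins, n_bins)
  agr <- matrix(0L, n_bins, n_bins)
  s <- sess$samples
  key <- paste(s$session, s$trial)
  for (i in seq_len(nrow(sess$layouts))) {
    ly <- sess$layouts[i, ]
    tr <- s[key == paste(ly$session, ly$trial) &
            s$t_ms >= ly$onset_ms & s$t_ms < ly$offset_ms & s$valid, ]
    for (what in c("face", "agr")) {
      cx <- ly[[paste0(what, "_cx")]]; cy <- ly[[paste0(what, "_cy")]]
      w <- ly[[paste0(what, "_w")]]; h <- ly[[paste0(what, "_h")]]
      inw <- in_rect(tr$x_deg, tr$y_deg, c(cx, cy, w, h))
      if (!any(inw)) next
      g <- gaze_heatmap(tr$x_deg[inw] - cx, tr$y_deg[inw] - cy, win,
                        n_bins = n_bins, smoothing_sigma_bins = 0)
      if (what == "face") face <- face + g$counts else agr <- agr + g$counts
    }
  }
  list(face = face, agr = agr)
}

heatmap_from_counts <- function(counts, window, sigma) {
  n_bins <- nrow(counts)
  xe <- seq(window[1] - window[3] / 2, window[1] + window[3] / 2,
            length.out = n_bins + 1)
  ye <- seq(window[2] - window[4] / 2, window[2] + window[4] / 2,
            length.out = n_bins + 1)
  structure(list(counts = counts, density = smooth_counts(counts, sigma),
                 x_edges = xe, y_edges = ye, window = window),
            class = "gaze_heatmap")
}

roi_percent_table <- function(fixations, config) {
  face_fix <- fixations[fixations$aoi == "face", , drop = FALSE]
  cells <- split(face_fix, interaction(face_fix[config$group_keys],
                                       drop = TRUE, sep = "\r"))
  rows <- lapply(cells, function(cell) {
    pct <- roi_fixation_percentages(cell)
    data.frame(cell[1, config$group_keys, drop = FALSE],
               roi = names(pct), percent = unname(pct), n_fix = nrow(cell),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pupil_summary_table <- function(fixations, config) {
  fx <- fixations[fixations$aoi %in% c("face", "agr") & !is.na(fixations$pupil_z), ]
  cells <- split(fx, interaction(fx[c(config$group_keys, "aoi")],
                                 drop = TRUE, sep = "\r"))
  rows <- lapply(cells, function(cell)
    data.frame(cell[1, c(config$group_keys, "aoi"), drop = FALSE],
               mean_pupil_au = mean(cell$pupil_au),
               mean_pupil_z = mean(cell$pupil_z),
               se_pupil_z = se_mean(cell$pupil_z), n_fix = nrow(cell),
               row.names = NULL, stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# The report's statistical battery over a trial-metrics table.
pipeline_stats <- function(metrics) {
  tests <- list()
  m <- metrics[metrics$total_fix > 0, , drop = FALSE]
  tests$face_vs_agr_fixations <-
    wilcoxon_signed_rank(m$n_fix_agr - m$n_fix_face)
  if (length(unique(m$image_sex)) == 2) {
    tests$female_vs_male_total <-
      wilcoxon_rank_sum(m$total_fix[m$image_sex == "female"],
                        m$total_fix[m$image_sex == "male"])
  }
  for (sx in unique(m$image_sex)) {
    fg <- m$first_gaze[m$image_sex == sx & m$first_gaze %in% c("face", "agr")]
    if (length(fg) >= 4)
      tests[[paste0("first_gaze_vs_half_", sx)]] <-
        chi2_proportion(sum(fg == "agr"), length(fg), 0.5)
  }
  anovas <- list()
  if (length(unique(m$treatment)) >= 2) {
    for (sx in unique(m$image_sex)) {
      msx <- m[m$image_sex == sx & !is.na(m$pagr), ]
      anovas[[paste0("pagr_by_treatment_", sx)]] <-
        anova_factorial(msx$pagr, data.frame(treatment = msx$treatment))
    }
    long <- rbind(
      data.frame(y = m$n_fix_face, image_sex = m$image_sex,
                 image_type = "face", treatment = m$treatment),
      data.frame(y = m$n_fix_agr, image_sex = m$image_sex,
                 image_type = "agr", treatment = m$treatment))
    if (length(unique(long$image_sex)) == 2) {
      anovas$threeway_fixations <- anova_factorial(
        long$y, long[c("image_sex", "image_type", "treatment")],
        include_interactions = TRUE)
    } else {
      anovas$twoway_fixations <- anova_factorial(
        long$y, long[c("image_type", "treatment")],
        include_interactions = TRUE)
    }
  }
  ok <- !is.na(m$pagr)
  corrs <- list(
    pagr_vs_nface = pearson_r(m$pagr[ok], m$n_fix_face[ok]),
    pagr_vs_nagr = pearson_r(m$pagr[ok], m$n_fix_agr[ok]),
    pagr_vs_total = pearson_r(m$pagr[ok], m$total_fix[ok]))
  list(tests = tests, anovas = anovas, correlations = corrs)
}

write_bundle <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(analysis$metrics, "trial_metrics.csv")
  w(analysis$fixations, "events.csv")
  w(analysis$summaries, "condition_summary.csv")
  w(analysis$roi_percentages, "roi_percentages.csv")
  w(analysis$pupil_summary, "pupil_summary.csv")
  utils::write.table(analysis$heatmaps$face$counts,
                     file.path(out_dir, "heatmap_face.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(analysis$heatmaps$agr$counts,
                     file.path(out_dir, "heatmap_agr.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  stat_rows <- do.call(rbind, c(
    lapply(analysis$stats$tests, as.data.frame),
    lapply(analysis$stats$correlations, as.data.frame)))
  w(stat_rows, "stats_tests.csv")
  anova_rows <- do.call(rbind, lapply(names(analysis$stats$anovas), function(nm) {
    a <- analysis$stats$anovas[[nm]]
    data.frame(analysis = nm, as.data.frame(a), stringsAsFactors = FALSE)
  }))
  if (!is.null(anova_rows)) w(anova_rows, "stats_anovas.csv")
  cfg <- analysis$config
  cfg_json <- jsonlite::toJSON(list(
    seed = cfg$seed, group_keys = cfg$group_keys,
    sessions = cfg$sessions, generator = unclass(cfg$generator),
    detector = unclass(cfg$detector)), auto_unbox = TRUE, digits = NA)
  prov <- list(seed = cfg$seed, config_hash = string_hash(as.character(cfg_json)),
               config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.gaze_analysis <- function(x, ...) {
  cat(sprintf("<gaze_analysis> %d sessions, %d trials, %d fixations\n",
              nrow(x$config$sessions), nrow(x$metrics), nrow(x$fixations)))
  pagr <- x$summaries[x$summaries$metric == "pagr", , drop = FALSE]
  if (nrow(pagr)) {
    cat("mean pAGR by condition:\n")
    for (i in seq_len(nrow(pagr)))
      cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n",
                  paste(unlist(pagr[i, x$config$group_keys]), collapse = "/"),
                  pagr$mean[i], pagr$se[i], pagr$n[i]))
  }
  invisible(x)
}

#' @export
summary.gaze_analysis <- function(object, ...) {
  print(object)
  cat("\nStatistical tests:\n")
  for (t in object$stats$tests) print(t)
  for (t in object$stats$correlations) print(t)
  invisible(object)
}

#' Render a human-readable analysis report
#'
#' Markdown tables (means +/- SE per condition, first-gaze proportions, ROI
#' percentages, pupil contrasts, test battery) assembled purely from the
#' bundle's tables — every number is traceable to a CSV row. Regeneration is
#' idempotent. Empty cells render as missing, never as zero.
#'
#' @param analysis a `gaze_analysis`.
#' @param path optional file to write the Markdown to.
#' @return the report as a character scalar (invisibly when written).
#' @export
make_report <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "gaze_analysis"))
  for (fld in c("metrics", "summaries", "roi_percentages", "pupil_summary", "stats"))
    if (is.null(analysis[[fld]])) stop_("analysis bundle is missing '%s'", fld)
  fmt <- function(v, d = 3) ifelse(is.na(v), "--", formatC(v, digits = d, format = "f"))
  keys <- analysis$config$group_keys
  lines <- c("# Gaze preference report", "",
             sprintf("Sessions: %d; trials: %d; seed: %d",
                     nrow(analysis$config$sessions), nrow(analysis$metrics),
                     analysis$config$seed), "")
  md_table <- function(df, headers, rows) {
    c(paste0("| ", paste(headers, collapse = " | "), " |"),
      paste0("|", paste(rep("---", length(headers)), collapse = "|"), "|"),
      vapply(rows, function(r) paste0("| ", paste(r, collapse = " | "), " |"),
             character(1)))
  }
  sm <- analysis$summaries
  for (metric in unique(sm$metric)) {
    sub <- sm[sm$metric == metric, , drop = FALSE]
    lines <- c(lines, sprintf("## %s (mean +/- s.e.m.)", metric), "",
               md_table(sub, c(keys, "mean", "se", "n"),
                        lapply(seq_len(nrow(sub)), function(i)
                          c(unlist(sub[i, keys]), fmt(sub$mean[i]),
                            fmt(sub$se[i]), sub$n[i]))), "")
  }
  rp <- analysis$roi_percentages
  lines <- c(lines, "## ROI fixation percentages", "",
             md_table(rp, c(keys, "roi", "percent", "n_fix"),
                      lapply(seq_len(nrow(rp)), function(i)
                        c(unlist(rp[i, keys]), rp$roi[i], fmt(rp$percent[i], 1),
                          rp$n_fix[i]))), "")
  pp <- analysis$pupil_summary
  lines <- c(lines, "## Pupil (z-scored against session baseline)", "",
             md_table(pp, c(keys, "aoi", "mean z", "se", "n_fix"),
                      lapply(seq_len(nrow(pp)), function(i)
                        c(unlist(pp[i, keys]), pp$aoi[i], fmt(pp$mean_pupil_z[i]),
                          fmt(pp$se_pupil_z[i]), pp$n_fix[i]))), "")
  lines <- c(lines, "## Statistical tests", "")
  for (nm in names(analysis$stats$tests)) {
    t <- analysis$stats$tests[[nm]]
    lines <- c(lines, sprintf("- %s [%s]: statistic %.4g, p = %.4g (%s)",
                              nm, t$name, t$statistic, t$p, t$method))
  }
  for (nm in names(analysis$stats$correlations)) {
    t <- analysis$stats$correlations[[nm]]
    lines <- c(lines, sprintf("- %s: r = %.3f, p = %.4g", nm, t$statistic, t$p))
  }
  for (nm in names(analysis$stats$anovas)) {
    a <- analysis$stats$anovas[[nm]]
    lines <- c(lines, "", sprintf("### ANOVA: %s (type-II SS)", nm), "",
               md_table(a, c("effect", "df", "F", "p"),
                        lapply(seq_len(nrow(a)), function(i)
                          c(a$effect[i], a$df[i], fmt(a$F[i], 2), fmt(a$p[i], 4)))))
  }
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
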
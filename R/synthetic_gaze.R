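#' Calibrate lognormal fixation-duration parameters from a mean and median
#'
#' For a lognormal with log-mean `mu` and log-sd `sigma`, the median is
#' `exp(mu)` and the mean `exp(mu + sigma^2/2)`. Inverting: `mu =
#' log(median)`, `sigma = sqrt(2 * log(mean/median))`. The returned
#' distribution therefore has exactly the requested mean and median.
#'
#' @param mean_ms target mean fixation duration (ms); must be >= `median_ms`.
#' @param median_ms target median fixation duration (ms), positive.
#' @return list with `mu` and `sigma` (log scale).
#' @examples
#' calibrate_lognormal(246.65, 213.00)
#' @export
calibrate_lognormal <- function(mean_ms, median_ms) {
  if (!is_scalar_number(mean_ms) || !is_scalar_number(median_ms) ||
      median_ms <= 0)
    stop_("mean_ms and median_ms must be positive numbers")
  if (mean_ms < median_ms)
    stop_("mean_ms (%g) < median_ms (%g): no real sigma exists", mean_ms, median_ms)
  list(mu = log(median_ms), sigma = sqrt(2 * log(mean_ms / median_ms)))
}

#' Synthetic gaze generator configuration
#'
#' Holds every generative parameter of the synthetic free-viewing sessions.
#' Defaults encode the study's behavioural structure: 3 s paired-image
#' displays at 1000 Hz preceded by a central-fixation baseline, alternating
#' ~200 ms fixations and 40 ms saccades, a per-fixation AGR-preference
#' probability `theta_pagr` and a first-gaze probability `q_first` per
#' treatment-by-image-sex condition (saline/OT/TE values for female images
#' 0.68/0.70/0.71 and 0.78/0.78/0.84; male images 0.69/0.69/0.70 and 0.81
#' throughout), fixation durations lognormal with mean 246.65 ms and median
#' 213.00 ms, ROI-concentrated landing points on faces, AOI-dependent pupil
#' size, and Poisson blinks.
#'
#' @param theta_pagr named list (`female`, `male`) of named vectors
#'   (`SL`, `OT`, `TE`): probability a non-initial fixation targets the AGR
#'   window.
#' @param q_first same shape: probability the first gaze targets AGR.
#' @param side_bias additive shift applied to the first-gaze AGR probability
#'   when the AGR image is on the left (and subtracted when on the right).
#' @param stay_prob optional probability of repeating the previous fixation's
#'   AOI; `NULL` (default) keeps targets i.i.d. so that the expected
#'   per-trial AGR proportion equals `theta_pagr` exactly.
#' @param duration_mu,duration_sigma lognormal fixation-duration parameters;
#'   defaults come from [calibrate_lognormal()] applied to
#'   `duration_mean_ms`/`duration_median_ms`.
#' @param duration_mean_ms,duration_median_ms calibration anchors (ms).
#' @param saccade_ms saccade transit duration (linear sweep).
#' @param roi_weights landing-point mixture over face ROIs
#'   (`forehead`, `eyes`, `nose`, `mouth`, `other`); must sum to 1.
#' @param pupil_base_mean,pupil_base_sd baseline pupil level (arbitrary
#'   units) and the SD of the per-trial baseline wander.
#' @param pupil_offsets named vector of additive pupil offsets per AOI, on
#'   the z scale of the session baseline (scaled internally by the total
#'   baseline SD).
#' @param pupil_noise_sd stationary SD of the AR(1) pupil noise (au).
#' @param pupil_ar1 AR(1) coefficient of the pupil noise.
#' @param blink_rate blinks per second; `blink_dur_ms` their duration.
#' @param trial_ms display duration; `baseline_ms` pre-stimulus central
#'   fixation; `iti_range_ms` jittered inter-trial gap (no samples emitted).
#' @param sample_rate_hz sampling rate; must divide 1000.
#' @param window_size_deg image-window side length; `window_ecc_deg`
#'   horizontal eccentricity of the window centres; `fix_window_deg` central
#'   fixation window side.
#' @param position_noise_sd optional Gaussian gaze-position noise SD (deg).
#' @param subject_room room identifier of the simulated subject (drives
#'   familiarity labels).
#' @param seed root seed; per-trial streams are derived by counter so any
#'   trial is reproducible in isolation.
#' @return object of class `gaze_config`.
#' @export
gaze_config <- function(theta_pagr = list(female = c(SL = 0.68, OT = 0.70, TE = 0.71),
                                          male   = c(SL = 0.69, OT = 0.69, TE = 0.70)),
                        q_first = list(female = c(SL = 0.78, OT = 0.78, TE = 0.84),
                                       male   = c(SL = 0.81, OT = 0.81, TE = 0.81)),
                        side_bias = 0,
                        stay_prob = NULL,
                        duration_mean_ms = 246.65,
                        duration_median_ms = 213.00,
                        duration_mu = NULL,
                        duration_sigma = NULL,
                        saccade_ms = 40,
                        roi_weights = c(forehead = 0.345, eyes = 0.35,
                                        nose = 0.12, mouth = 0.08, other = 0.105),
                        pupil_base_mean = 2000,
                        pupil_base_sd = 80,
                        pupil_offsets = c(face = 0, agr = -0.3),
                        pupil_noise_sd = 60,
                        pupil_ar1 = 0.95,
                        blink_rate = 0.1,
                        blink_dur_ms = 100,
                        trial_ms = 3000,
                        baseline_ms = 500,
                        iti_range_ms = c(2000, 3000),
                        sample_rate_hz = 1000,
                        window_size_deg = 8,
                        window_ecc_deg = 8,
                        fix_window_deg = 3,
                        position_noise_sd = 0,
                        subject_room = "R1",
                        seed = 1) {
  if (is.null(duration_mu) || is.null(duration_sigma)) {
    cal <- calibrate_lognormal(duration_mean_ms, duration_median_ms)
    duration_mu <- duration_mu %||% cal$mu
    duration_sigma <- duration_sigma %||% cal$sigma
  }
  for (sx in c("female", "male")) {
    for (p in theta_pagr[[sx]]) if (!is_probability(p))
      stop_("theta_pagr[%s] values must be probabilities in [0,1]", sx)
    for (p in q_first[[sx]]) if (!is_probability(p))
      stop_("q_first[%s] values must be probabilities in [0,1]", sx)
  }
  if (duration_sigma < 0) stop_("duration_sigma must be >= 0")
  if (sample_rate_hz <= 0 || 1000 %% sample_rate_hz != 0)
    stop_("sample_rate_hz must be positive and divide 1000")
  if (abs(sum(roi_weights) - 1) > 1e-8) stop_("roi_weights must sum to 1")
  if (any(roi_weights < 0)) stop_("roi_weights must be non-negative")
  if (!setequal(names(roi_weights), c("forehead", "eyes", "nose", "mouth", "other")))
    stop_("roi_weights must name forehead, eyes, nose, mouth, other")
  if (!is.null(stay_prob) && !is_probability(stay_prob))
    stop_("stay_prob must be a probability or NULL")
  if (blink_rate < 0 || blink_dur_ms <= 0) stop_("invalid blink parameters")
  if (trial_ms < 1000 * exp(duration_mu - 4 * max(duration_sigma, 0.1)) / 1000)
    stop_("trial_ms too short to contain a single minimal fixation")
  if (trial_ms <= saccade_ms) stop_("trial_ms too short for one saccade + fixation")
  stopifnot(is_scalar_number(seed))
  structure(
    list(theta_pagr = theta_pagr, q_first = q_first, side_bias = side_bias,
         stay_prob = stay_prob,
         duration_mu = duration_mu, duration_sigma = duration_sigma,
         duration_mean_ms = duration_mean_ms, duration_median_ms = duration_median_ms,
         saccade_ms = saccade_ms, roi_weights = roi_weights,
         pupil_base_mean = pupil_base_mean, pupil_base_sd = pupil_base_sd,
         pupil_offsets = pupil_offsets, pupil_noise_sd = pupil_noise_sd,
         pupil_ar1 = pupil_ar1, blink_rate = blink_rate,
         blink_dur_ms = blink_dur_ms, trial_ms = trial_ms,
         baseline_ms = baseline_ms, iti_range_ms = iti_range_ms,
         sample_rate_hz = sample_rate_hz, window_size_deg = window_size_deg,
         window_ecc_deg = window_ecc_deg, fix_window_deg = fix_window_deg,
         position_noise_sd = position_noise_sd, subject_room = subject_room,
         seed = as.integer(seed)),
    class = "gaze_config")
}

#' @export
print.gaze_config <- function(x, ...) {
  cat(sprintf(paste0("<gaze_config> %d ms trials @ %d Hz, durations lognormal",
                     "(mu=%.4f, sigma=%.4f), seed %d\n"),
              x$trial_ms, x$sample_rate_hz, x$duration_mu, x$duration_sigma, x$seed))
  invisible(x)
}

# Condition lookup helpers ---------------------------------------------------

cond_param <- function(tbl, image_sex, treatment, what) {
  v <- tbl[[image_sex]]
  if (is.null(v) || is.na(v[treatment]))
    stop_("no %s value for condition %s/%s", what, image_sex, treatment)
  unname(v[treatment])
}

# Build the trial layout implied by a plan entry and a config.
layout_for_trial <- function(entry, config, session_id, onset_ms, monkeys = NULL) {
  w <- config$window_size_deg
  ecc <- config$window_ecc_deg
  face_cx <- if (entry$face_side == "left") -ecc else ecc
  agr_cx <- -face_cx
  cls <- list(age_class = NA_character_, familiarity = NA_character_)
  sex <- NA_character_
  if (!is.null(monkeys)) {
    row <- monkeys[monkeys$id == entry$monkey_id, , drop = FALSE]
    if (nrow(row) == 1L) {
      cls <- classify_identity(row, config$subject_room)
      sex <- row$sex
    }
  }
  data.frame(session = session_id, trial = entry$trial,
             onset_ms = onset_ms, offset_ms = onset_ms + config$trial_ms,
             face_cx = face_cx, face_cy = 0, face_w = w, face_h = w,
             agr_cx = agr_cx, agr_cy = 0, agr_w = w, agr_h = w,
             fix_cx = 0, fix_cy = 0,
             fix_w = config$fix_window_deg, fix_h = config$fix_window_deg,
             monkey_id = entry$monkey_id, image_sex = sex,
             age_class = cls$age_class, familiarity = cls$familiarity,
             treatment = entry$treatment %||% NA_character_,
             face_side = entry$face_side,
             face_image = entry$face_image, agr_image = entry$agr_image,
             stringsAsFactors = FALSE)
}

# Draw a landing point for one fixation.
draw_landing <- function(aoi, layout, config, roi_map) {
  if (aoi == "agr") {
    list(x = stats::runif(1, layout$agr_cx - layout$agr_w / 2,
                          layout$agr_cx + layout$agr_w / 2),
         y = stats::runif(1, layout$agr_cy - layout$agr_h / 2,
                          layout$agr_cy + layout$agr_h / 2),
         roi = NA_character_)
  } else {
    w <- config$roi_weights
    roi <- sample(names(w), 1L, prob = w)
    pt <- sample_point_in_roi(roi_map, roi)
    list(x = pt[1], y = pt[2], roi = roi)
  }
}

#' Simulate one free-viewing trial
#'
#' Emits the trial's 1000 Hz sample log (pre-stimulus central-fixation
#' baseline followed by exactly `trial_ms`-worth of display samples) and the
#' matching ground-truth fixation record. The first display fixation's
#' target is Bernoulli(`q_first`, shifted by `side_bias`); subsequent targets
#' are i.i.d. Bernoulli(`theta_pagr`) between the AGR and face windows
#' (or a stay/switch chain when `stay_prob` is set). Fixation durations are
#' lognormal, saccades linear sweeps, pupil an AR(1) process with
#' AOI-dependent offsets, and blinks zero-pupil gaps.
#'
#' @param entry one-row list/data frame with `trial`, `monkey_id`,
#'   `face_image`, `agr_image`, `face_side`, and (for condition lookup)
#'   `treatment` and `image_sex`.
#' @param config a [gaze_config()].
#' @param layout optional precomputed one-row layout; built from `entry`
#'   when `NULL`.
#' @param session_id session label stamped into the log.
#' @param t0 absolute time (ms) at which the trial's baseline starts.
#' @param trial_seed integer seed for this trial's stream; derived from
#'   `config$seed` and the trial index when `NULL`.
#' @return list with `samples` (data frame: `session`, `trial`, `t_ms`,
#'   `x_deg`, `y_deg`, `pupil_au`, `valid`), `truth` (one row per true
#'   fixation: onset/offset, AOI, ROI, landing point, first-gaze flag) and
#'   `layout`.
#' @export
simulate_trial <- function(entry, config, layout = NULL, session_id = "S1",
                           t0 = 0, trial_seed = NULL) {
  stopifnot(inherits(config, "gaze_config"))
  entry <- as.list(entry)
  treatment <- entry$treatment %||% "SL"
  image_sex <- entry$image_sex %||% "female"
  theta <- cond_param(config$theta_pagr, image_sex, treatment, "theta_pagr")
  q <- cond_param(config$q_first, image_sex, treatment, "q_first")
  if (is.null(layout))
    layout <- layout_for_trial(c(entry, list(treatment = treatment)),
                               config, session_id, t0 + config$baseline_ms)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(trial_seed %||% derive_seed(config$seed, entry$trial %||% 1))

  dt <- 1000 / config$sample_rate_hz
  n_base <- round(config$baseline_ms / dt)
  n_disp <- round(config$trial_ms / dt)
  n_sac <- max(1L, round(config$saccade_ms / dt))
  roi_map <- default_roi_map(c(layout$face_cx, layout$face_cy,
                               layout$face_w, layout$face_h))

  # side-bias shifts the first-gaze AGR probability toward the left side
  agr_left <- layout$face_side == "right"
  q_eff <- min(1, max(0, q + config$side_bias * (if (agr_left) 1 else -1)))

  x <- numeric(n_disp); y <- numeric(n_disp)
  fix_on <- integer(0); fix_off <- integer(0)
  fix_aoi <- character(0); fix_roi <- character(0)
  fix_x <- numeric(0); fix_y <- numeric(0)
  seg_aoi <- character(n_disp)  # AOI driving the pupil offset, "" elsewhere

  cursor <- 0L  # samples of display emitted so far
  prev <- c(0, 0)
  k <- 0L
  prev_aoi <- NA_character_
  while (cursor < n_disp) {
    k <- k + 1L
    if (k == 1L) {
      aoi <- if (stats::runif(1) < q_eff) "agr" else "face"
    } else if (!is.null(config$stay_prob)) {
      aoi <- if (stats::runif(1) < config$stay_prob) prev_aoi
             else if (stats::runif(1) < theta) "agr" else "face"
    } else {
      aoi <- if (stats::runif(1) < theta) "agr" else "face"
    }
    land <- draw_landing(aoi, layout, config, roi_map)
    # saccade sweep toward the landing point
    n_s <- min(n_sac, n_disp - cursor)
    if (n_s > 0) {
      fr <- seq_len(n_s) / (n_sac + 1)
      x[cursor + seq_len(n_s)] <- prev[1] + fr * (land$x - prev[1])
      y[cursor + seq_len(n_s)] <- prev[2] + fr * (land$y - prev[2])
      cursor <- cursor + n_s
    }
    if (cursor >= n_disp) break
    dur <- stats::rlnorm(1, config$duration_mu, config$duration_sigma)
    n_f <- max(1L, round(dur / dt))
    n_f <- min(n_f, n_disp - cursor)
    x[cursor + seq_len(n_f)] <- land$x
    y[cursor + seq_len(n_f)] <- land$y
    seg_aoi[cursor + seq_len(n_f)] <- aoi
    fix_on <- c(fix_on, cursor); fix_off <- c(fix_off, cursor + n_f)
    fix_aoi <- c(fix_aoi, aoi); fix_roi <- c(fix_roi, land$roi)
    fix_x <- c(fix_x, land$x); fix_y <- c(fix_y, land$y)
    cursor <- cursor + n_f
    prev <- c(land$x, land$y)
    prev_aoi <- aoi
  }

  n_tot <- n_base + n_disp
  x_all <- c(rep(0, n_base), x)
  y_all <- c(rep(0, n_base), y)
  aoi_all <- c(rep("", n_base), seg_aoi)

  # pupil: per-trial baseline wander + AOI offset (scaled to the total
  # baseline SD) + stationary AR(1) noise
  s_total <- sqrt(config$pupil_base_sd^2 + config$pupil_noise_sd^2)
  level <- config$pupil_base_mean + stats::rnorm(1, 0, config$pupil_base_sd)
  off <- rep(0, n_tot)
  for (a in names(config$pupil_offsets))
    off[aoi_all == a] <- config$pupil_offsets[[a]] * s_total
  phi <- config$pupil_ar1
  if (config$pupil_noise_sd > 0) {
    innov <- stats::rnorm(n_tot, 0, config$pupil_noise_sd * sqrt(1 - phi^2))
    noise <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = stats::rnorm(1, 0, config$pupil_noise_sd)))
  } else noise <- rep(0, n_tot)
  pupil <- level + off + noise

  if (config$position_noise_sd > 0) {
    x_all <- x_all + stats::rnorm(n_tot, 0, config$position_noise_sd)
    y_all <- y_all + stats::rnorm(n_tot, 0, config$position_noise_sd)
  }

  valid <- rep(TRUE, n_tot)
  if (config$blink_rate > 0) {
    n_blink <- stats::rpois(1, config$blink_rate * n_tot * dt / 1000)
    if (n_blink > 0) {
      starts <- sort(sample.int(n_tot, n_blink))
      n_b <- round(config$blink_dur_ms / dt)
      for (s in starts) {
        idx <- s:min(n_tot, s + n_b - 1L)
        valid[idx] <- FALSE
      }
    }
  }
  pupil[!valid] <- 0
  x_all[!valid] <- NA_real_
  y_all[!valid] <- NA_real_

  t_ms <- t0 + (seq_len(n_tot) - 1L) * dt
  onset <- t0 + n_base * dt
  samples <- data.frame(session = session_id, trial = entry$trial %||% 1L,
                        t_ms = t_ms, x_deg = x_all, y_deg = y_all,
                        pupil_au = pupil, valid = valid,
                        stringsAsFactors = FALSE)
  truth <- if (length(fix_on)) {
    data.frame(session = session_id, trial = entry$trial %||% 1L,
               fix_index = seq_along(fix_on),
               onset_ms = onset + fix_on * dt, offset_ms = onset + fix_off * dt,
               aoi = fix_aoi, roi = fix_roi, x_deg = fix_x, y_deg = fix_y,
               first_gaze = c(fix_aoi[1], rep(NA_character_, length(fix_on) - 1L)),
               treatment = treatment, image_sex = image_sex,
               stringsAsFactors = FALSE)
  } else {
    data.frame(session = character(0), trial = integer(0), fix_index = integer(0),
               onset_ms = numeric(0), offset_ms = numeric(0), aoi = character(0),
               roi = character(0), x_deg = numeric(0), y_deg = numeric(0),
               first_gaze = character(0), treatment = character(0),
               image_sex = character(0), stringsAsFactors = FALSE)
  }
  list(samples = samples, truth = truth, layout = layout)
}

#' Simulate a whole session from a plan
#'
#' Loops [simulate_trial()] over the plan's trial list with jittered
#' inter-trial gaps (timestamps jump; no inter-trial samples are emitted) and
#' monotone absolute timestamps. Each trial uses a seed derived from
#' `config$seed` and the trial index, so any trial can be re-simulated in
#' isolation.
#'
#' @param plan a [build_session_plan()] result.
#' @param config a [gaze_config()].
#' @param catalogue optional `gaze_catalogue` supplying monkey attributes for
#'   identity-class labels in the layouts.
#' @return object of class `gaze_session`: list with `samples`, `truth`,
#'   `layouts` data frames plus `plan` and `config`.
#' @export
simulate_session <- function(plan, config, catalogue = NULL) {
  stopifnot(inherits(plan, "session_plan"), inherits(config, "gaze_config"))
  monkeys <- if (!is.null(catalogue)) catalogue$monkeys else NULL
  image_sex <- plan$set_label
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, 500000 + nrow(plan$trials)))
  itis <- round(stats::runif(nrow(plan$trials), config$iti_range_ms[1],
                             config$iti_range_ms[2]))
  t0 <- 0
  out_s <- vector("list", nrow(plan$trials))
  out_t <- vector("list", nrow(plan$trials))
  out_l <- vector("list", nrow(plan$trials))
  for (i in seq_len(nrow(plan$trials))) {
    entry <- c(as.list(plan$trials[i, ]),
               list(treatment = plan$treatment, image_sex = image_sex))
    layout <- layout_for_trial(entry, config, plan$session_id,
                               t0 + config$baseline_ms, monkeys)
    tr <- simulate_trial(entry, config, layout = layout,
                         session_id = plan$session_id, t0 = t0,
                         trial_seed = derive_seed(config$seed, entry$trial))
    out_s[[i]] <- tr$samples; out_t[[i]] <- tr$truth; out_l[[i]] <- tr$layout
    t0 <- t0 + config$baseline_ms + config$trial_ms + itis[i]
  }
  structure(list(samples = do.call(rbind, out_s),
                 truth = do.call(rbind, out_t),
                 layouts = do.call(rbind, out_l),
                 plan = plan, config = config),
            class = "gaze_session")
}

#' @export
print.gaze_session <- function(x, ...) {
  cat(sprintf("<gaze_session> %s: %d trials, %d samples, %d true fixations\n",
              x$plan$session_id, nrow(x$plan$trials), nrow(x$samples),
              nrow(x$truth)))
  invisible(x)
}
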
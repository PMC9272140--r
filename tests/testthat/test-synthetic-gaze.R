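test_that("lognormal calibration reproduces the requested mean and median", {
  cal <- calibrate_lognormal(246.65, 213.00)
  expect_equal(cal$mu, log(213), tolerance = 1e-10)
  expect_equal(cal$sigma, sqrt(2 * log(246.65 / 213)), tolerance = 1e-10)
  expect_equal(cal$sigma, 0.5416, tolerance = 1e-4)
  # cross-check by numeric moment integration
  mean_num <- stats::integrate(function(x) x * stats::dlnorm(x, cal$mu, cal$sigma),
                               0, Inf, rel.tol = 1e-10)$value
  expect_equal(mean_num, 246.65, tolerance = 1e-6)
  expect_equal(stats::qlnorm(0.5, cal$mu, cal$sigma), 213.00, tolerance = 1e-8)

  expect_equal(calibrate_lognormal(200, 200), list(mu = log(200), sigma = 0))
  cal2 <- calibrate_lognormal(2 * 7, 7)
  expect_equal(cal2$mu, log(7))
  expect_equal(cal2$sigma, sqrt(2 * log(2)), tolerance = 1e-10)
  expect_equal(cal2$sigma, 1.1774, tolerance = 1e-4)
  expect_error(calibrate_lognormal(100, 200), "no real sigma")
})

test_that("a trial emits exactly the display-period samples and is deterministic", {
  cfg <- gaze_config(seed = 3, blink_rate = 0)
  entry <- list(trial = 1L, monkey_id = "A", face_image = "f", agr_image = "a",
                face_side = "left", treatment = "SL", image_sex = "female")
  tr1 <- simulate_trial(entry, cfg)
  tr2 <- simulate_trial(entry, cfg)
  expect_identical(tr1$samples, tr2$samples)
  expect_identical(tr1$truth, tr2$truth)
  disp <- tr1$samples$t_ms >= tr1$layout$onset_ms &
    tr1$samples$t_ms < tr1$layout$offset_ms
  expect_equal(sum(disp), 3000)
  expect_equal(nrow(tr1$samples), 3500)  # incl. 500 ms baseline
  expect_false(is.unsorted(tr1$samples$t_ms, strictly = TRUE))
})

test_that("degenerate preference puts every non-initial fixation on the AGR window", {
  cfg <- gaze_config(seed = 5, blink_rate = 0,
                     theta_pagr = list(female = c(SL = 1, OT = 1, TE = 1),
                                       male = c(SL = 1, OT = 1, TE = 1)),
                     q_first = list(female = c(SL = 1, OT = 1, TE = 1),
                                    male = c(SL = 1, OT = 1, TE = 1)))
  entry <- list(trial = 2L, monkey_id = "A", face_image = "f", agr_image = "a",
                face_side = "left", treatment = "SL", image_sex = "female")
  tr <- simulate_trial(entry, cfg)
  expect_true(all(tr$truth$aoi == "agr"))
  agr_win <- c(tr$layout$agr_cx, tr$layout$agr_cy, tr$layout$agr_w, tr$layout$agr_h)
  expect_true(all(abs(tr$truth$x_deg - agr_win[1]) <= agr_win[3] / 2))
})

test_that("noise-free pupil equals the baseline level throughout", {
  cfg <- gaze_config(seed = 9, blink_rate = 0, pupil_noise_sd = 0,
                     pupil_base_sd = 0, pupil_offsets = c(face = 0, agr = 0))
  entry <- list(trial = 1L, monkey_id = "A", face_image = "f", agr_image = "a",
                face_side = "right", treatment = "SL", image_sex = "female")
  tr <- simulate_trial(entry, cfg)
  expect_true(all(tr$samples$pupil_au == cfg$pupil_base_mean))
})

test_that("sampled durations match the calibration anchors at large n", {
  cfg <- gaze_config(seed = 1)
  set.seed(17)
  draws <- stats::rlnorm(1e5, cfg$duration_mu, cfg$duration_sigma)
  expect_equal(mean(draws), 246.65, tolerance = 0.02)
  expect_equal(stats::median(draws), 213.00, tolerance = 0.02)
})

test_that("session structure: per-trial truth, monotone time, renewal-rate fixation count", {
  sess <- quick_session(seed = 21, n_trials = 12)
  expect_equal(length(unique(sess$truth$trial)), 12)
  expect_false(is.unsorted(sess$samples$t_ms, strictly = TRUE))
  expect_gte(nrow(sess$samples), 12 * 3000)
  # renewal expectation: ~ trial_ms / (mean duration + saccade_ms) ~ 10.5
  per_trial <- table(sess$truth$trial)
  expect_gt(mean(per_trial), 8)
  expect_lt(mean(per_trial), 13)
  # truth intervals contain samples at the recorded landing point
  tr <- sess$truth[sess$truth$trial == sess$truth$trial[1], ][2, ]
  s <- sess$samples[sess$samples$trial == tr$trial &
                    sess$samples$t_ms >= tr$onset_ms &
                    sess$samples$t_ms < tr$offset_ms & sess$samples$valid, ]
  expect_true(all(abs(s$x_deg - tr$x_deg) < 1e-9))
})

test_that("truth-level pAGR and first-gaze frequencies recover the generative values", {
  cfg <- gaze_config(seed = 33, blink_rate = 0,
                     q_first = list(female = c(SL = 0.68, OT = 0.68, TE = 0.68),
                                    male = c(SL = 0.81, OT = 0.81, TE = 0.81)))
  # q_first set equal to theta so E[per-trial pAGR] = theta exactly
  n <- 400
  pagr <- numeric(n); first <- character(n)
  for (k in seq_len(n)) {
    entry <- list(trial = k, monkey_id = "A", face_image = "f", agr_image = "a",
                  face_side = if (k %% 2) "left" else "right",
                  treatment = "SL", image_sex = "female")
    tr <- simulate_trial(entry, cfg)
    pagr[k] <- mean(tr$truth$aoi == "agr")
    first[k] <- tr$truth$aoi[1]
  }
  se_pagr <- stats::sd(pagr) / sqrt(n)
  expect_lt(abs(mean(pagr) - 0.68), 3 * se_pagr + 1e-12)
  se_first <- sqrt(0.68 * 0.32 / n)
  expect_lt(abs(mean(first == "agr") - 0.68), 3 * se_first)
})

test_that("per-image fixation count and dwell move together across trials", {
  # the count-vs-dwell coupling operates per image: trials with more
  # fixations on an image accumulate proportionally more dwell on it
  sess <- quick_session(seed = 8, n_trials = 40)
  per_trial <- split(sess$truth, sess$truth$trial)
  n_agr <- vapply(per_trial, function(d) sum(d$aoi == "agr"), numeric(1))
  dwell_agr <- vapply(per_trial, function(d)
    sum((d$offset_ms - d$onset_ms)[d$aoi == "agr"]), numeric(1))
  n_face <- vapply(per_trial, function(d) sum(d$aoi == "face"), numeric(1))
  dwell_face <- vapply(per_trial, function(d)
    sum((d$offset_ms - d$onset_ms)[d$aoi == "face"]), numeric(1))
  # pooled over trial-by-image cells, as the count and dwell panels pair up
  expect_gt(stats::cor(c(n_face, n_agr), c(dwell_face, dwell_agr)), 0.8)
  expect_gt(stats::cor(n_agr, dwell_agr), 0.4)
  expect_gt(stats::cor(n_face, dwell_face), 0.4)
})
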
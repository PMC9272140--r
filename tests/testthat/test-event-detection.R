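make_series <- function(x, y, t = seq_along(x) - 1, pupil = 2000, valid = TRUE) {
  n <- length(x)
  data.frame(session = rep("T", n), trial = rep(1L, n), t_ms = t, x_deg = x,
             y_deg = y, pupil_au = rep_len(pupil, n),
             valid = rep_len(valid, n), stringsAsFactors = FALSE)
}

test_that("blink padding, clipping and merging follow the interval rules", {
  p <- detector_params(blink_pad_ms = 50)
  s <- make_series(rep(0, 400), rep(0, 400))
  s$pupil_au[s$t_ms >= 100 & s$t_ms < 150] <- 0
  b <- detect_blinks(s, p)
  expect_equal(b, data.frame(onset_ms = 50, offset_ms = 200))

  expect_equal(nrow(detect_blinks(make_series(rep(0, 100), rep(0, 100)), p)), 0)

  # two zero-runs 10 ms apart merge after 50 ms padding; check against a
  # brute-force interval-union oracle
  s2 <- make_series(rep(0, 500), rep(0, 500))
  s2$pupil_au[s2$t_ms >= 100 & s2$t_ms < 120] <- 0
  s2$pupil_au[s2$t_ms >= 130 & s2$t_ms < 160] <- 0
  b2 <- detect_blinks(s2, p)
  expect_equal(nrow(b2), 1)
  expect_equal(b2, oracle_interval_union(c(100 - 50, 130 - 50),
                                         c(120 + 50, 160 + 50), 0, 500))

  # clipping at the series edges
  s3 <- make_series(rep(0, 100), rep(0, 100))
  s3$pupil_au[s3$t_ms < 20] <- 0
  expect_equal(detect_blinks(s3, p)$onset_ms, 0)
})

test_that("I-DT segments a two-dwell sweep trace as the oracle dictates", {
  p <- detector_params(dispersion_deg = 1.0, min_duration_ms = 60)
  x <- c(rep(0, 100), seq_len(20) * 0.5, rep(10, 150))
  s <- make_series(x, rep(0, length(x)))
  fx <- detect_fixations(s, p)
  orc <- oracle_idt(s$t_ms, s$x_deg, s$y_deg, 1.0, 60)
  expect_equal(nrow(fx), 2)
  expect_equal(fx$onset_ms, orc$onset_ms)
  expect_equal(fx$offset_ms, orc$offset_ms)
  expect_equal(fx$x_deg, orc$x_deg, tolerance = 1e-12)
  # the dwells are recovered to within a few sweep samples
  expect_equal(fx$duration_ms[1], 100, tolerance = 0.05)
  expect_equal(fx$duration_ms[2], 150, tolerance = 0.05)
  expect_lt(abs(fx$x_deg[1] - 0), 0.1)
  expect_lt(abs(fx$x_deg[2] - 10), 0.1)
})

test_that("constant and sub-threshold traces behave at the margins", {
  p <- detector_params(dispersion_deg = 1.0, min_duration_ms = 60)
  s <- make_series(rep(2, 300), rep(-1, 300))
  fx <- detect_fixations(s, p)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 300)
  expect_equal(fx$onset_ms, 0)
  expect_equal(fx$offset_ms, 300)
  expect_equal(c(fx$x_deg, fx$y_deg), c(2, -1))

  expect_equal(nrow(detect_fixations(make_series(rep(0, 50), rep(0, 50)), p)), 0)
  expect_equal(nrow(detect_fixations(make_series(numeric(0), numeric(0)), p)), 0)
})

test_that("I-DT equals the from-scratch oracle on random traces (pre-merge)", {
  p <- detector_params()
  set.seed(99)
  for (k in 1:25) {
    s <- random_trace(sample(200:900, 1))
    fx <- detect_fixations(s, p, merge = FALSE)
    orc <- oracle_idt(s$t_ms, s$x_deg, s$y_deg, p$dispersion_deg,
                      p$min_duration_ms)
    expect_identical(nrow(fx), nrow(orc))
    expect_equal(fx$onset_ms, orc$onset_ms)
    expect_equal(fx$offset_ms, orc$offset_ms)
    expect_equal(fx$x_deg, orc$x_deg, tolerance = 1e-12)
    expect_equal(fx$y_deg, orc$y_deg, tolerance = 1e-12)
  }
})

# Adjacent true fixations whose landing points sit within one dispersion
# window (x-range + y-range <= threshold, sweep included since it is linear)
# are indistinguishable from one fixation by construction; collapse them
# before comparing detected events with truth.
collapse_truth <- function(truth, dispersion = 1.0) {
  if (nrow(truth) < 2) return(truth)
  out <- truth[1, ]
  for (i in 2:nrow(truth)) {
    last <- nrow(out)
    if (abs(truth$x_deg[i] - out$x_deg[last]) +
        abs(truth$y_deg[i] - out$y_deg[last]) <= dispersion) {
      out$offset_ms[last] <- truth$offset_ms[i]
    } else {
      out <- rbind(out, truth[i, ])
    }
  }
  out
}

test_that("detection recovers ground truth on clean (noise- and blink-free) trials", {
  cfg <- gaze_config(seed = 41, blink_rate = 0)
  n_checked <- 0
  for (k in 1:15) {
    entry <- list(trial = k, monkey_id = "A", face_image = "f", agr_image = "a",
                  face_side = "left", treatment = "SL", image_sex = "female")
    tr <- simulate_trial(entry, cfg)
    durs <- tr$truth$offset_ms - tr$truth$onset_ms
    # skip trials where the detector may legitimately disagree with a naive
    # reading of truth: durations near the min-duration threshold, a final
    # truncated fixation too short to detect, or consecutive landings within
    # one dispersion window
    if (any(durs > 45 & durs < 75)) next
    if (durs[length(durs)] < 80) next
    if (nrow(collapse_truth(tr$truth)) != nrow(tr$truth)) next
    disp <- tr$samples[tr$samples$t_ms >= tr$layout$onset_ms &
                       tr$samples$t_ms < tr$layout$offset_ms, ]
    fx <- detect_fixations(disp, detector_params())
    truth <- tr$truth
    n_checked <- n_checked + 1
    expect_equal(nrow(fx), nrow(truth))
    # boundaries recovered to within one saccade transit (slow sweeps keep
    # their tails inside the dispersion window)
    expect_true(all(abs(fx$onset_ms - truth$onset_ms) <= 45))
    expect_true(all(abs(fx$offset_ms - truth$offset_ms) <= 45))
  }
  expect_gte(n_checked, 5)
})

test_that("fixations never span an injected blink", {
  cfg <- gaze_config(seed = 42, blink_rate = 0)
  entry <- list(trial = 1L, monkey_id = "A", face_image = "f", agr_image = "a",
                face_side = "left", treatment = "SL", image_sex = "female")
  tr <- simulate_trial(entry, cfg)
  disp <- tr$samples[tr$samples$t_ms >= tr$layout$onset_ms &
                     tr$samples$t_ms < tr$layout$offset_ms, ]
  truth <- tr$truth
  i <- which.max(truth$offset_ms - truth$onset_ms)
  mid <- floor((truth$onset_ms[i] + truth$offset_ms[i]) / 2)
  cut <- disp$t_ms >= mid & disp$t_ms < mid + 120
  disp$valid[cut] <- FALSE
  disp$pupil_au[cut] <- 0
  fx2 <- detect_fixations(disp, detector_params())
  blk <- detect_blinks(disp, detector_params())
  expect_equal(nrow(blk), 1)
  inside <- fx2$onset_ms < blk$offset_ms & fx2$offset_ms > blk$onset_ms
  expect_false(any(inside))
})

test_that("duration recovery survives moderate position noise", {
  # 0.02 deg i.i.d. sample noise; final truncated fixation per trial excluded.
  # (Independent per-sample jitter accumulates into the window's range, so the
  # usable i.i.d. noise level sits well below dispersion itself; see the
  # methods vignette.)
  cfg <- gaze_config(seed = 77, blink_rate = 0, position_noise_sd = 0.02)
  durs <- numeric(0)
  for (k in 1:20) {
    entry <- list(trial = k, monkey_id = "A", face_image = "f", agr_image = "a",
                  face_side = "left", treatment = "SL", image_sex = "female")
    tr <- simulate_trial(entry, cfg)
    disp <- tr$samples[tr$samples$t_ms >= tr$layout$onset_ms &
                       tr$samples$t_ms < tr$layout$offset_ms, ]
    fx <- detect_fixations(disp, detector_params())
    if (nrow(fx) > 1) durs <- c(durs, fx$duration_ms[-nrow(fx)])
  }
  expect_lt(abs(mean(durs) - 246.65) / 246.65, 0.05)
})

test_that("saccades exactly fill inter-fixation gaps", {
  fx <- data.frame(onset_ms = c(0, 140, 375), offset_ms = c(100, 340, 500),
                   x_deg = c(0, 5, -3), y_deg = c(0, 1, 2))
  sc <- derive_saccades(fx)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$duration_ms, c(40, 35))
  expect_equal(sc$x_start, c(0, 5))
  expect_equal(sc$x_end, c(5, -3))
  expect_equal(nrow(derive_saccades(fx[1, ])), 0)
  bad <- fx; bad$onset_ms[2] <- 50
  expect_error(derive_saccades(bad), "overlapping")
})
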
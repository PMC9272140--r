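# Small fixtures built in code at test time.

mini_catalogue <- function(pairs = 3) {
  monkeys <- data.frame(id = c("A", "B"), sex = "female",
                        age_years = c(7, 15), room = c("R1", "R2"),
                        stringsAsFactors = FALSE)
  images <- list(
    A = list(face = sprintf("A_face_%d", 1:pairs),
             agr = sprintf("A_agr_%d", 1:pairs)),
    B = list(face = sprintf("B_face_%d", 1:pairs),
             agr = sprintf("B_agr_%d", 1:pairs)))
  stimulus_catalogue("female", monkeys, images)
}

# A deterministic layout row for constructed-fixture tests: face window on
# the left at (-8, 0), AGR on the right at (8, 0), both 8x8 deg.
fixture_layout <- function(face_side = "left", onset = 500, trial = 1L) {
  ecc <- if (face_side == "left") -8 else 8
  data.frame(session = "T", trial = trial, onset_ms = onset,
             offset_ms = onset + 3000,
             face_cx = ecc, face_cy = 0, face_w = 8, face_h = 8,
             agr_cx = -ecc, agr_cy = 0, agr_w = 8, agr_h = 8,
             fix_cx = 0, fix_cy = 0, fix_w = 3, fix_h = 3,
             monkey_id = "A", image_sex = "female", age_class = "young",
             familiarity = "familiar", treatment = "SL",
             face_side = face_side, face_image = "A_face_1",
             agr_image = "A_agr_1", stringsAsFactors = FALSE)
}

# Fixation rows for constructed metric tests.
fixture_fixations <- function(aoi, durations = rep(200, length(aoi)),
                              onset0 = 540, gap = 40) {
  n <- length(aoi)
  onsets <- onset0 + cumsum(c(0, utils::head(durations, -1) + gap))[seq_len(n)]
  x <- ifelse(aoi == "face", -8, ifelse(aoi == "agr", 8, 0))
  data.frame(trial = rep(1L, n), onset_ms = onsets,
             offset_ms = onsets + durations,
             duration_ms = durations, x_deg = x, y_deg = rep(0, n),
             pupil_au = rep(2000, n), n_samples = durations,
             stringsAsFactors = FALSE)
}

quick_session <- function(seed = 1, n_trials = 12, treatment = "SL",
                          config = NULL) {
  cat2 <- mini_catalogue(pairs = ceiling(n_trials / 2))
  plan <- build_session_plan(cat2, "M1", treatment, seed = seed)
  plan$trials <- plan$trials[seq_len(n_trials), , drop = FALSE]
  config <- config %||% gaze_config(seed = seed)
  simulate_session(plan, config, cat2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
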
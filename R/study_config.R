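#' Construct a stimulus catalogue
#'
#' A catalogue describes one image set (all-female or all-male stimulus
#' monkeys): the monkeys' identity attributes and, per monkey, equal-length
#' vectors of face and anogenital-region (AGR) image ids.
#'
#' @param set_label `"female"` or `"male"`; must match every monkey's sex.
#' @param monkeys data frame with columns `id`, `sex` (`"female"`/`"male"`),
#'   `age_years` (positive), `room` (housing-room identifier).
#' @param images named list (one element per monkey id), each a list with
#'   character vectors `face` and `agr` of equal length.
#' @return An object of class `gaze_catalogue`.
#' @export
stimulus_catalogue <- function(set_label, monkeys, images) {
  if (!set_label %in% c("female", "male"))
    stop_("set_label must be 'female' or 'male', got '%s'", set_label)
  req <- c("id", "sex", "age_years", "room")
  miss <- setdiff(req, names(monkeys))
  if (length(miss))
    stop_("monkeys table is missing field(s): %s", paste(miss, collapse = ", "))
  monkeys$id <- as.character(monkeys$id)
  if (anyDuplicated(monkeys$id))
    stop_("duplicate monkey id(s): %s",
          paste(unique(monkeys$id[duplicated(monkeys$id)]), collapse = ", "))
  if (any(!monkeys$sex %in% c("female", "male")))
    stop_("field 'sex' must be 'female' or 'male'")
  if (any(!is.finite(monkeys$age_years)) || any(monkeys$age_years <= 0))
    stop_("field 'age_years' must be positive for every monkey")
  if (any(is.na(monkeys$room)) || any(!nzchar(as.character(monkeys$room))))
    stop_("field 'room' must be non-empty for every monkey")
  if (any(monkeys$sex != set_label))
    stop_("sex/set mismatch: monkey(s) %s are not %s",
          paste(monkeys$id[monkeys$sex != set_label], collapse = ", "), set_label)
  if (!setequal(names(images), monkeys$id))
    stop_("images must list exactly the catalogue's monkey ids")
  n_pairs <- NULL
  for (id in monkeys$id) {
    im <- images[[id]]
    if (is.null(im$face) || is.null(im$agr))
      stop_("images for monkey %s need both 'face' and 'agr' ids", id)
    if (length(im$face) != length(im$agr))
      stop_("monkey %s has %d face ids but %d AGR ids (must be equal)",
            id, length(im$face), length(im$agr))
    n_pairs <- c(n_pairs, length(im$face))
  }
  structure(
    list(set_label = set_label, monkeys = monkeys,
         images = images[monkeys$id],
         pairs_per_monkey = unname(n_pairs[1])),
    class = "gaze_catalogue")
}

#' @export
print.gaze_catalogue <- function(x, ...) {
  cat(sprintf("<gaze_catalogue> %s set: %d monkeys x %d image pairs (%d trials/session)\n",
              x$set_label, nrow(x$monkeys), x$pairs_per_monkey,
              nrow(x$monkeys) * x$pairs_per_monkey))
  invisible(x)
}

#' Built-in stimulus catalogues
#'
#' Catalogues mirroring the study design: a female set of 6 stimulus monkeys
#' and a male set of 9, each with 20 face/AGR image pairs. Monkey ids and
#' room co-residence follow the colony description; individual ages are
#' synthetic values spanning the reported 6-23 (female) and 6-22 (male) year
#' ranges, since per-monkey ages are not public. Monkeys housed with the
#' subjects (room `"R1"`) are the familiar ones.
#'
#' @param set_label `"female"` or `"male"`.
#' @param pairs_per_monkey image pairs per monkey (default 20).
#' @return A `gaze_catalogue`.
#' @export
default_catalogue <- function(set_label = c("female", "male"),
                              pairs_per_monkey = 20) {
  set_label <- match.arg(set_label)
  if (set_label == "female") {
    monkeys <- data.frame(
      id = c("B", "C", "F", "HD", "HP", "SR"),
      sex = "female",
      age_years = c(7, 10, 12, 6, 18, 23),
      room = c("R2", "R2", "R1", "R2", "R2", "R2"),
      stringsAsFactors = FALSE)
  } else {
    monkeys <- data.frame(
      id = c("AM", "AR", "BR", "CN", "HK", "HL", "OK", "PN", "TM"),
      sex = "male",
      age_years = c(6, 8, 10, 13, 7, 16, 20, 22, 9),
      room = c("R2", "R2", "R1", "R1", "R2", "R1", "R1", "R1", "R2"),
      stringsAsFactors = FALSE)
  }
  images <- lapply(monkeys$id, function(id) {
    list(face = sprintf("%s_face_%02d", id, seq_len(pairs_per_monkey)),
         agr  = sprintf("%s_agr_%02d",  id, seq_len(pairs_per_monkey)))
  })
  names(images) <- monkeys$id
  stimulus_catalogue(set_label, monkeys, images)
}

#' Classify a stimulus monkey's identity relative to a subject
#'
#' Age classes partition at 9 years: younger than 9 is `"young"`, 9 or older
#' is `"old"` (skeletal maturity is reached by about age 8, so a 9-year-old
#' is treated as mature). Familiarity is room co-residence: a monkey housed
#' in the subject's room, hence in constant visual and auditory contact with
#' it, is `"familiar"`.
#'
#' @param monkey one-row data frame or list with `id`, `age_years`, `room`.
#' @param subject_room the subject's housing-room identifier.
#' @return list with `age_class` (`"young"`/`"old"`) and `familiarity`
#'   (`"familiar"`/`"unfamiliar"`).
#' @export
classify_identity <- function(monkey, subject_room) {
  id <- monkey$id %||% "<unnamed>"
  age <- monkey$age_years
  room <- monkey$room
  if (is.null(age) || length(age) != 1L || is.na(age))
    stop_("cannot classify monkey %s: missing age", id)
  if (age <= 0) stop_("cannot classify monkey %s: non-positive age", id)
  if (is.null(room) || length(room) != 1L || is.na(room))
    stop_("cannot classify monkey %s: missing room", id)
  if (missing(subject_room) || is.null(subject_room) || is.na(subject_room))
    stop_("cannot classify monkey %s: missing subject room", id)
  list(age_class = if (age < 9) "young" else "old",
       familiarity = if (identical(as.character(room),
                                   as.character(subject_room)))
         "familiar" else "unfamiliar")
}

#' Build a randomized session plan
#'
#' Produces the trial list for one session: every face and every AGR image of
#' the catalogue appears exactly once. Within each stimulus monkey the
#' face/AGR pairing is shuffled (any face image may appear beside any AGR
#' image of the same monkey), trial order is uniformly shuffled across
#' monkeys and images, and the side carrying the face image is a fair
#' independent coin flip per trial. Deterministic given `seed`.
#'
#' @param catalogue a `gaze_catalogue`.
#' @param subject_id subject label recorded in the plan.
#' @param treatment `"SL"`, `"OT"` or `"TE"`.
#' @param seed integer seed, recorded in the plan for provenance.
#' @param session_id optional session label.
#' @return An object of class `session_plan`: a list with `trials` (data
#'   frame: `trial`, `monkey_id`, `face_image`, `agr_image`, `face_side`)
#'   plus the identifying metadata.
#' @export
build_session_plan <- function(catalogue, subject_id, treatment = c("SL", "OT", "TE"),
                               seed, session_id = NULL) {
  treatment <- match.arg(treatment)
  if (!inherits(catalogue, "gaze_catalogue")) stop_("catalogue must be a gaze_catalogue")
  if (nrow(catalogue$monkeys) == 0L) stop_("empty catalogue")
  stopifnot(is_scalar_number(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0))
  per_monkey <- lapply(catalogue$monkeys$id, function(id) {
    im <- catalogue$images[[id]]
    data.frame(monkey_id = id,
               face_image = sample(im$face),
               agr_image = sample(im$agr),
               stringsAsFactors = FALSE)
  })
  trials <- do.call(rbind, per_monkey)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  trials$face_side <- sample(c("left", "right"), nrow(trials), replace = TRUE)
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials <- trials[, c("trial", "monkey_id", "face_image", "agr_image", "face_side")]
  structure(
    list(session_id = session_id %||% sprintf("%s_%s_%s_seed%d",
                                              subject_id, catalogue$set_label,
                                              treatment, as.integer(seed)),
         subject_id = subject_id, treatment = treatment,
         set_label = catalogue$set_label, seed = as.integer(seed),
         trials = trials),
    class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %s: subject %s, %s treatment, %d trials (seed %d)\n",
              x$session_id, x$subject_id, x$treatment, nrow(x$trials), x$seed))
  invisible(x)
}

#' Read / write catalogues and session plans as JSON
#'
#' `load_catalogue()` validates all catalogue invariants on read and fails
#' with the offending field named.
#'
#' @param path file path.
#' @return `load_catalogue()` a `gaze_catalogue`; `load_session_plan()` a
#'   `session_plan`.
#' @export
load_catalogue <- function(path) {
  if (!file.exists(path)) stop_("catalogue file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (fld in c("set_label", "monkeys", "images"))
    if (is.null(raw[[fld]])) stop_("catalogue is missing field '%s'", fld)
  monkeys <- do.call(rbind, lapply(raw$monkeys, function(m) {
    for (fld in c("id", "sex", "age_years", "room"))
      if (is.null(m[[fld]])) stop_("monkey entry is missing field '%s'", fld)
    data.frame(id = as.character(m$id), sex = as.character(m$sex),
               age_years = as.numeric(m$age_years), room = as.character(m$room),
               stringsAsFactors = FALSE)
  }))
  images <- lapply(raw$images, function(im)
    list(face = as.character(unlist(im$face)), agr = as.character(unlist(im$agr))))
  stimulus_catalogue(raw$set_label, monkeys, images)
}

#' @rdname load_catalogue
#' @param catalogue a `gaze_catalogue` to serialize.
#' @export
write_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "gaze_catalogue"))
  out <- list(set_label = catalogue$set_label,
              monkeys = lapply(seq_len(nrow(catalogue$monkeys)), function(i)
                as.list(catalogue$monkeys[i, ])),
              images = catalogue$images)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname load_catalogue
#' @export
load_session_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("subject_id", "treatment", "set_label", "seed", "trials"))
    if (is.null(raw[[fld]])) stop_("session plan is missing field '%s'", fld)
  structure(list(session_id = raw$session_id, subject_id = raw$subject_id,
                 treatment = raw$treatment, set_label = raw$set_label,
                 seed = as.integer(raw$seed),
                 trials = as.data.frame(raw$trials, stringsAsFactors = FALSE)),
            class = "session_plan")
}

#' @rdname load_catalogue
#' @param plan a `session_plan` to serialize.
#' @export
write_session_plan <- function(plan, path) {
  stopifnot(inherits(plan, "session_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# Save/restore the global RNG state so seeded helpers do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
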
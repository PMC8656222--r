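#' Parameters for a synthetic screening cohort
#'
#' Bundles the knobs of the cohort generator. Disease truth is assigned at
#' eye level: each eye is independently ever-affected with probability
#' `1 - sqrt(1 - p_referable_patient)`, so that the probability a patient
#' ever develops referable retinopathy in at least one eye equals
#' `p_referable_patient`. An affected eye has an onset year drawn uniformly
#' over the visit schedule; with `progression = TRUE` (default) the eye is
#' referable from onset onwards, emulating the persistence of
#' vision-threatening disease, otherwise only in the onset year.
#'
#' @param n_patients Number of patients (>= 1).
#' @param years Strictly increasing integer visit years.
#' @param p_referable_patient Probability a patient ever has referable
#'   disease.
#' @param p_ungradable Per-image probability an image is ungradable; a
#'   scalar or one value per year.
#' @param progression Logical: once referable, stays referable.
#' @param attendance Probability a patient attends each visit year; scalar
#'   or one value per year (baseline screening programmes see attrition).
#' @param severity_probs Category probabilities within referable eye-years,
#'   named `R2`, `R3a`, `R3s`.
#' @param background_prob Probability a non-referable eye-year is R1
#'   (background retinopathy) rather than R0.
#' @param ungradable_referable_or Odds ratio linking ungradability to
#'   referable status (1 = independent, the default; the generator is
#'   silent evidence either way).
#' @param rng_seed Integer seed; all substreams derive from it.
#' @return An object of class `dr_cohort_params`.
#' @export
cohort_params <- function(n_patients,
                          years,
                          p_referable_patient = 0.02,
                          p_ungradable = 0.0223,
                          progression = TRUE,
                          attendance = 1,
                          severity_probs = c(R2 = 0.85, R3a = 0.10, R3s = 0.05),
                          background_prob = 0.10,
                          ungradable_referable_or = 1,
                          rng_seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (length(years) == 0 || any(diff(years) <= 0)) {
    stop("`years` must be non-empty and strictly increasing", call. = FALSE)
  }
  probs <- c(p_referable_patient, p_ungradable, attendance, background_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!length(p_ungradable) %in% c(1L, length(years))) {
    stop("`p_ungradable` must be a scalar or one value per year", call. = FALSE)
  }
  if (!length(attendance) %in% c(1L, length(years))) {
    stop("`attendance` must be a scalar or one value per year", call. = FALSE)
  }
  stopifnot(setequal(names(severity_probs), c("R2", "R3a", "R3s")),
            abs(sum(severity_probs) - 1) < 1e-8)
  structure(list(
    n_patients = as.integer(n_patients),
    years = as.integer(years),
    p_referable_patient = p_referable_patient,
    p_ungradable = rep_len(p_ungradable, length(years)),
    progression = isTRUE(progression),
    attendance = rep_len(attendance, length(years)),
    severity_probs = severity_probs[c("R2", "R3a", "R3s")],
    background_prob = background_prob,
    ungradable_referable_or = ungradable_referable_or,
    rng_seed = as.integer(rng_seed)
  ), class = "dr_cohort_params")
}

#' Cohort parameters emulating an annual two-field screening programme
#'
#' Defaults mirror a government-employee screening cohort: ~4,900 patients
#' photographed at a 2009 baseline, annual follow-up 2011-2017 with
#' declining attendance, two fields per eye per visit, per-year ungradable
#' fractions between 2.2% and 7.1%, and roughly 1% image-level referable
#' prevalence.
#'
#' @param n_patients Number of patients (default 4900).
#' @param rng_seed Integer seed.
#' @param ... Overrides passed on to [cohort_params()].
#' @return A `dr_cohort_params`.
#' @export
annual_screening_params <- function(n_patients = 4900, rng_seed = 1L, ...) {
  defaults <- list(
    n_patients = n_patients,
    years = c(2009L, 2011:2017),
    p_referable_patient = 0.04,
    p_ungradable = c(0.0223, 0.0271, 0.0304, 0.0414,
                     0.0706, 0.0640, 0.0472, 0.0494),
    attendance = c(1, 3505, 3325, 3198, 3104, 3038, 2873, 2579) /
      c(1, rep(4900, 7)),
    rng_seed = rng_seed
  )
  do.call(cohort_params, modifyList(defaults, list(...)))
}

#' Expected image-level referable fraction of a parameter set
#'
#' Closed form under the generator's truth model: each eye is ever-affected
#' with probability `1 - sqrt(1 - p_referable_patient)`, onset is uniform
#' over the visit schedule, and (with monotone progression) an affected eye
#' is referable at visit `j` of `k` with probability `j / k`. The expected
#' image-level fraction is the attendance-weighted average of those
#' per-year probabilities. At the [annual_screening_params()] defaults
#' this is ~1%.
#'
#' @param params A [cohort_params()].
#' @return Expected fraction of images whose true grade is referable.
#' @export
expected_referable_fraction <- function(params) {
  stopifnot(inherits(params, "dr_cohort_params"))
  k <- length(params$years)
  p_eye <- 1 - sqrt(1 - params$p_referable_patient)
  p_year <- if (params$progression) seq_len(k) / k else rep(1 / k, k)
  a <- params$attendance
  p_eye * sum(a * p_year) / sum(a)
}

#' Simulate a longitudinal screening cohort
#'
#' Generates one row per fundus photograph: two eyes times two fields (F1
#' disc-centred, F2 macula-centred) per attended patient-year. Both fields
#' of an eye-year share the true grade (disease status is an eye property).
#' Classifier scores are drawn from `classifier` conditional on referable
#' status for gradable images only; ungradable images carry `NA` scores.
#' Fully deterministic given `params$rng_seed`: truth, quality and score
#' draws use independent named substreams.
#'
#' @param params A [cohort_params()] object.
#' @param classifier A [calibrate_classifier()] model (default: binormal at
#'   AUC 0.953 with threshold 0.485 anchored to a 1.45% flag rate).
#' @return A tibble of class `dr_cohort` with columns `image_id`,
#'   `patient_id`, `visit_year`, `eye`, `field`, `true_grade`, `gradable`,
#'   `score`, carrying the generating `params` and `classifier` as
#'   attributes.
#' @export
#' @examples
#' p <- cohort_params(n_patients = 10, years = 2009, p_ungradable = 0)
#' co <- simulate_cohort(p)
#' nrow(co)  # 10 patients x 2 eyes x 2 fields = 40
simulate_cohort <- function(params, classifier = calibrate_classifier(0.953)) {
  stopifnot(inherits(params, "dr_cohort_params"),
            inherits(classifier, "dr_classifier"))
  n <- params$n_patients
  years <- params$years
  k <- length(years)
  patient_id <- sprintf("P%05d", seq_len(n))

  ## -- truth substream: eye-level ever-affected status, onset, severity --
  truth <- with_seed(substream_seed(params$rng_seed, "truth"), {
    p_eye <- 1 - sqrt(1 - params$p_referable_patient)
    eyes <- tibble::tibble(
      patient_id = rep(patient_id, each = 2L),
      eye = rep(c("left", "right"), n),
      affected = runif(2L * n) < p_eye,
      onset_idx = sample.int(k, 2L * n, replace = TRUE),
      severity = sample(names(params$severity_probs), 2L * n, replace = TRUE,
                        prob = params$severity_probs)
    )
    bg <- matrix(runif(2L * n * k) < params$background_prob, ncol = k)
    attend <- matrix(runif(n * k) <
                       rep(params$attendance, each = n), ncol = k)
    list(eyes = eyes, bg = bg, attend = attend)
  })

  eyes <- truth$eyes
  year_idx <- rep(seq_len(k), times = nrow(eyes))
  eye_year <- tibble::tibble(
    patient_id = rep(eyes$patient_id, each = k),
    eye = rep(eyes$eye, each = k),
    visit_year = rep(years, times = nrow(eyes)),
    year_idx = year_idx,
    affected = rep(eyes$affected, each = k),
    onset_idx = rep(eyes$onset_idx, each = k),
    severity = rep(eyes$severity, each = k),
    bg = as.vector(t(truth$bg))
  )
  referable_now <- eye_year$affected &
    if (params$progression) eye_year$year_idx >= eye_year$onset_idx
    else eye_year$year_idx == eye_year$onset_idx
  eye_year$true_grade <- ifelse(
    referable_now, eye_year$severity,
    ifelse(eye_year$bg, "R1", "R0")
  )

  # attendance is a patient-year property
  attend_long <- tibble::tibble(
    patient_id = rep(patient_id, times = k),
    visit_year = rep(years, each = n),
    attended = as.vector(truth$attend)
  )
  eye_year <- dplyr::inner_join(eye_year, attend_long,
                                by = c("patient_id", "visit_year"))
  eye_year <- eye_year[eye_year$attended, ]

  ## -- expand to images: two fields per eye-year --
  images <- tibble::tibble(
    patient_id = rep(eye_year$patient_id, each = 2L),
    visit_year = rep(eye_year$visit_year, each = 2L),
    eye = rep(eye_year$eye, each = 2L),
    field = rep(c("F1", "F2"), nrow(eye_year)),
    true_grade = rep(eye_year$true_grade, each = 2L),
    year_idx = rep(eye_year$year_idx, each = 2L)
  )
  images$image_id <- paste(images$patient_id, images$visit_year,
                           substr(images$eye, 1, 1), images$field, sep = "_")

  ## -- quality substream --
  images$gradable <- with_seed(substream_seed(params$rng_seed, "quality"), {
    p_u <- params$p_ungradable[images$year_idx]
    if (params$ungradable_referable_or != 1) {
      ref <- is_referable(images$true_grade)
      odds <- p_u / (1 - p_u) *
        ifelse(ref, params$ungradable_referable_or, 1)
      p_u <- odds / (1 + odds)
    }
    runif(nrow(images)) >= p_u
  })

  ## -- score substream --
  images$score <- NA_real_
  images$score[images$gradable] <-
    with_seed(substream_seed(params$rng_seed, "scores"),
              draw_scores(classifier,
                          is_referable(images$true_grade[images$gradable])))

  out <- images[order(images$patient_id, images$visit_year,
                      images$eye, images$field),
                c("image_id", "patient_id", "visit_year", "eye", "field",
                  "true_grade", "gradable", "score")]
  new_cohort(out, params = params, classifier = classifier)
}

new_cohort <- function(df, params = NULL, classifier = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "params") <- params
  attr(out, "classifier") <- classifier
  class(out) <- c("dr_cohort", class(out))
  validate_cohort(out)
}

#' Validate a cohort's structural invariants
#'
#' Checks that `(patient_id, visit_year, eye, field)` is unique, grades are
#' valid NHS labels, and a score is present if and only if the image is
#' gradable. Called on construction and on load.
#'
#' @param cohort A `dr_cohort` (or any data frame with the cohort columns).
#' @return The cohort, invisibly usable in a pipe; errors on violation.
#' @export
validate_cohort <- function(cohort) {
  need <- c("image_id", "patient_id", "visit_year", "eye", "field",
            "true_grade", "gradable", "score")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(cohort$patient_id, cohort$visit_year, cohort$eye, cohort$field)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, year, eye, field) combinations", call. = FALSE)
  }
  if (anyDuplicated(cohort$image_id)) {
    stop("duplicate image_id", call. = FALSE)
  }
  assert_grade(cohort$true_grade)
  if (!all(is.na(cohort$score) == !cohort$gradable)) {
    stop("score must be present iff image is gradable", call. = FALSE)
  }
  if (any(!is.na(cohort$score) & (cohort$score < 0 | cohort$score > 1))) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  cohort
}

# YAML-safe serialisation: named vectors become maps, not bare sequences
params_to_list <- function(params) {
  out <- unclass(params)
  out$severity_probs <- as.list(out$severity_probs)
  out
}

#' Patient index of a cohort
#'
#' @param cohort A `dr_cohort`.
#' @return A named list mapping each `patient_id` to its `image_id`s; every
#'   image appears in exactly one entry (the grouping of images by patient).
#' @export
cohort_index <- function(cohort) {
  split(cohort$image_id, cohort$patient_id)
}

#' @export
print.dr_cohort <- function(x, ...) {
  cat("<dr_cohort> ", nrow(x), " images, ",
      length(unique(x$patient_id)), " patients, years ",
      paste(range(x$visit_year), collapse = "-"),
      "; ungradable ", sum(!x$gradable),
      " (", sprintf("%.2f%%", 100 * mean(!x$gradable)), ")",
      ", referable ", sum(is_referable(x$true_grade)),
      " (", sprintf("%.2f%%", 100 * mean(is_referable(x$true_grade))), ")\n",
      sep = "")
  NextMethod()
}

#' Write / read a cohort as CSV with a YAML parameter sidecar
#'
#' The cohort is stored as a flat CSV (one row per image); the generating
#' parameters travel in `<path>.yaml`. [read_cohort()] re-validates all
#' structural invariants on load.
#'
#' @param cohort A `dr_cohort`.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `dr_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as.data.frame(cohort), path, progress = FALSE)
  params <- attr(cohort, "params")
  if (!is.null(params)) {
    yaml::write_yaml(params_to_list(params), paste0(path, ".yaml"),
                     precision = 17)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      image_id = "c", patient_id = "c", visit_year = "i", eye = "c",
      field = "c", true_grade = "c", gradable = "l", score = "d"
    )
  )
  sidecar <- paste0(path, ".yaml")
  params <- NULL
  if (file.exists(sidecar)) {
    raw <- yaml::read_yaml(sidecar)
    raw$severity_probs <- unlist(raw$severity_probs)
    raw$p_ungradable <- unlist(raw$p_ungradable)
    raw$attendance <- unlist(raw$attendance)
    raw$years <- unlist(raw$years)
    params <- do.call(cohort_params, raw)
  }
  new_cohort(df, params = params)
}
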
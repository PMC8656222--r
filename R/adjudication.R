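#' Configuration of the reference-standard adjudication panel
#'
#' A panel of trained graders reads each selected image independently; if
#' all agree on referable status the consensus stands, otherwise an
#' assigned senior ophthalmologist's reading is conclusive. The default
#' senior is error-free (the reference standard by fiat); a fallible
#' senior is available for sensitivity analyses.
#'
#' @param panel List of [grader_profile()]s (default: three trained
#'   graders with sensitivity 0.90 and specificity 0.95 each).
#' @param senior A single senior [grader_profile()] (default perfect).
#' @param rng_seed Seed for all grading draws.
#' @return An object of class `dr_adjudication_config`.
#' @export
adjudication_config <- function(panel = NULL, senior = NULL, rng_seed = 1L) {
  if (is.null(panel)) {
    panel <- lapply(1:3, function(i)
      grader_profile(paste0("G", i), sens_h = 0.90, spec_h = 0.95))
  }
  if (is.null(senior)) {
    senior <- grader_profile("SENIOR", sens_h = 1, spec_h = 1,
                             is_senior = TRUE)
  }
  if (!length(panel) || !all(vapply(panel, inherits, TRUE, "dr_grader"))) {
    stop("`panel` must be a non-empty list of grader profiles", call. = FALSE)
  }
  if (!inherits(senior, "dr_grader") || !senior$is_senior) {
    stop("`senior` must be a grader profile with `is_senior = TRUE`",
         call. = FALSE)
  }
  structure(list(panel = panel, senior = senior,
                 rng_seed = as.integer(rng_seed)),
            class = "dr_adjudication_config")
}

#' Adjudicate reference-standard grades for a set of images
#'
#' For each gradable image, each panel member grades independently given
#' the truth (via [grade_by_human()]); if the panel is unanimous on
#' referable status the result is a `CONSENSUS` reference with the modal
#' category on the agreed side (ties broken towards the more severe
#' category), otherwise the senior's own reading is returned with path
#' `SENIOR`. Deterministic given `cfg$rng_seed`.
#'
#' @param images A data frame with `image_id`, `true_grade` and `gradable`
#'   (typically a selected subset of a `dr_cohort`). Ungradable rows are an
#'   error: adjudication requires a readable photograph.
#' @param cfg An [adjudication_config()].
#' @return A tibble with columns `image_id`, `grade`, `path`
#'   (`CONSENSUS`/`SENIOR`) and `n_graders_used`.
#' @export
adjudicate_images <- function(images, cfg = adjudication_config()) {
  stopifnot(inherits(cfg, "dr_adjudication_config"))
  if (any(!images$gradable)) {
    stop("cannot adjudicate ungradable images", call. = FALSE)
  }
  n <- nrow(images)
  k <- length(cfg$panel)
  if (n == 0L) {
    return(tibble::tibble(image_id = character(), grade = character(),
                          path = character(), n_graders_used = integer()))
  }
  with_seed(substream_seed(cfg$rng_seed, "graders"), {
    draws <- vapply(cfg$panel, function(g)
      grade_by_human(images$true_grade, g), character(n))
    draws <- matrix(draws, nrow = n)
    ref_status <- matrix(is_referable(as.vector(draws)), nrow = n)
    unanimous <- rowSums(ref_status) %in% c(0L, k)
    senior_draw <- grade_by_human(images$true_grade, cfg$senior)

    grade <- character(n)
    grade[!unanimous] <- senior_draw[!unanimous]
    if (any(unanimous)) {
      sev <- setNames(seq_along(grade_levels()), grade_levels())
      grade[unanimous] <- apply(draws[unanimous, , drop = FALSE], 1,
                                function(g) {
        tab <- table(g)
        winners <- names(tab)[tab == max(tab)]
        winners[which.max(sev[winners])]
      })
    }
    tibble::tibble(
      image_id = images$image_id,
      grade = grade,
      path = ifelse(unanimous, "CONSENSUS", "SENIOR"),
      n_graders_used = ifelse(unanimous, k, k + 1L)
    )
  })
}
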
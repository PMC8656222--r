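#' Define a human grader's error profile
#'
#' Human graders are modelled as imperfect binary classifiers of referable
#' status: a referable image is called referable with probability `sens_h`,
#' a non-referable image is called non-referable with probability `spec_h`.
#' Within the correct side the grader copies the true category; on the
#' wrong side a configured default category is returned (`R1` for a missed
#' referable image, `R2` for a false alarm), since the binary endpoint is
#' what the workflow consumes.
#'
#' @param grader_id Character identifier.
#' @param sens_h,spec_h Per-grader sensitivity and specificity for the
#'   referable/non-referable call, in `[0, 1]`.
#' @param is_senior Logical; senior adjudicators resolve panel disagreement.
#' @return An object of class `dr_grader`.
#' @export
#' @examples
#' grader_profile("G1", sens_h = 0.9, spec_h = 0.95)
grader_profile <- function(grader_id, sens_h = 1, spec_h = 1,
                           is_senior = FALSE) {
  stopifnot(is.character(grader_id), length(grader_id) == 1L)
  if (!is.numeric(sens_h) || sens_h < 0 || sens_h > 1 ||
      !is.numeric(spec_h) || spec_h < 0 || spec_h > 1) {
    stop("`sens_h` and `spec_h` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(grader_id = grader_id, sens_h = sens_h, spec_h = spec_h,
                 is_senior = isTRUE(is_senior)),
            class = "dr_grader")
}

#' @export
print.dr_grader <- function(x, ...) {
  cat("<dr_grader>", x$grader_id,
      if (x$is_senior) "(senior)" else "",
      " sens:", x$sens_h, " spec:", x$spec_h, "\n")
  invisible(x)
}

#' Simulate human grading of images
#'
#' Draws one grade per image from a grader's error model, conditional on
#' the true grade. With probability `sens_h` (truth referable) or `spec_h`
#' (truth non-referable) the returned label's referable status matches the
#' truth and the exact category is copied; otherwise the wrong-side default
#' is returned.
#'
#' @param true_grade Character vector of true NHS grades (see
#'   [grade_levels()]).
#' @param grader A `dr_grader`.
#' @param gradable Logical vector; grading an ungradable image is an error.
#' @param miss_label Category returned when a referable image is missed
#'   (default `"R1"`).
#' @param false_alarm_label Category returned when a non-referable image is
#'   called referable (default `"R2"`).
#' @return Character vector of graded labels, same length as `true_grade`.
#'   Uses the current RNG state.
#' @export
#' @examples
#' set.seed(1)
#' g <- grader_profile("G1", sens_h = 0.9, spec_h = 0.95)
#' grade_by_human(c("R2", "R0", "R3a"), g)
grade_by_human <- function(true_grade, grader,
                           gradable = rep(TRUE, length(true_grade)),
                           miss_label = "R1", false_alarm_label = "R2") {
  stopifnot(inherits(grader, "dr_grader"))
  assert_grade(true_grade)
  stopifnot(is_referable(false_alarm_label), !is_referable(miss_label))
  if (any(!gradable)) {
    stop("cannot human-grade an ungradable image", call. = FALSE)
  }
  ref <- is_referable(true_grade)
  p_correct <- ifelse(ref, grader$sens_h, grader$spec_h)
  correct <- runif(length(true_grade)) < p_correct
  out <- true_grade
  out[!correct & ref]  <- miss_label
  out[!correct & !ref] <- false_alarm_label
  out
}
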
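#' NHS retinopathy grade labels
#'
#' The UK National Health Service screening taxonomy used throughout the
#' package: R0 (no retinopathy), R1 (background), R2 (pre-proliferative),
#' R3a (active proliferative), R3s (stable treated proliferative).
#' Vision-threatening *referable* retinopathy is R2 or worse.
#'
#' @return `grade_levels()` returns the five labels in severity order.
#' @export
grade_levels <- function() c("R0", "R1", "R2", "R3a", "R3s")

#' @rdname grade_levels
#' @param grade Character vector of grade labels.
#' @return `is_referable()` returns a logical vector: `TRUE` for R2/R3a/R3s,
#'   `FALSE` for R0/R1. Unknown labels are an error.
#' @export
#' @examples
#' is_referable(c("R0", "R1", "R2", "R3a", "R3s"))
is_referable <- function(grade) {
  bad <- setdiff(unique(grade), grade_levels())
  if (length(bad)) {
    stop("unknown grade label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  grade %in% c("R2", "R3a", "R3s")
}

assert_grade <- function(grade) {
  invisible(is_referable(grade))
}
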
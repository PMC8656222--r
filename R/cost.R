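#' Per-image time and cost parameters for grading strategies
#'
#' @param t_machine Minutes of machine time per automatically graded image
#'   (default 0.058).
#' @param t_human Minutes of human-grader time per manually graded image
#'   (default 0.368).
#' @param c_human Payment per human-graded image in currency units
#'   (default 0.172 USD).
#' @param machine_marginal_cost Currency per machine-graded image; defaults
#'   to 0 because the marginal cost of running a trained classifier is
#'   negligible next to grader remuneration (development cost is out of
#'   scope).
#' @return An object of class `dr_cost_params`.
#' @export
cost_params <- function(t_machine = 0.058, t_human = 0.368, c_human = 0.172,
                        machine_marginal_cost = 0) {
  vals <- c(t_machine, t_human, c_human, machine_marginal_cost)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all cost parameters must be non-negative", call. = FALSE)
  }
  structure(list(t_machine = t_machine, t_human = t_human, c_human = c_human,
                 machine_marginal_cost = machine_marginal_cost),
            class = "dr_cost_params")
}

#' Time and cost of fully-human, fully-automated and semi-automated grading
#'
#' Totals are linear in counts: the fully human strategy grades all
#' `n_total` images by hand; the fully automated strategy grades all of
#' them by machine; the semi-automated strategy runs the machine over all
#' images and humans over the `n_reviewed` flagged images only. Saving
#' fractions compare semi-automated against fully human:
#' `1 - semi / fully_human` per dimension. Two versions are reported:
#' the canonical fraction at full precision, and a printed-precision
#' reproduction computed after rounding per-image minutes to
#' `round_time_digits` decimals and per-image cost to `round_cost_digits`
#' decimals — the form in which such figures circulate in programme
#' reports, where rounding visibly shifts the headline percentage.
#'
#' @param n_total Total number of images to grade.
#' @param n_reviewed Number of images flagged for human review
#'   (`<= n_total`).
#' @param params A [cost_params()].
#' @param round_time_digits,round_cost_digits Report precision used for the
#'   printed-precision saving fractions (defaults 2 and 3).
#' @return An object of class `dr_cost_report`: a list with a `strategies`
#'   tibble (columns `strategy`, `total_time_h`, `mean_time_min_per_image`,
#'   `total_cost`, `mean_cost_per_image`) and scalars
#'   `saving_time_fraction`, `saving_cost_fraction`,
#'   `saving_time_fraction_printed`, `saving_cost_fraction_printed`.
#' @export
#' @examples
#' cost_evaluate(88363, 8975,
#'               cost_params(t_machine = 84.8 * 60 / 88363,
#'                           t_human = 55 * 60 / 8975,
#'                           c_human = 1544 / 8975))
cost_evaluate <- function(n_total, n_reviewed, params = cost_params(),
                          round_time_digits = 2, round_cost_digits = 3) {
  stopifnot(inherits(params, "dr_cost_params"))
  if (n_reviewed > n_total || n_total < 0 || n_reviewed < 0) {
    stop("need 0 <= n_reviewed <= n_total", call. = FALSE)
  }
  time_min <- c(
    fully_human = n_total * params$t_human,
    fully_auto = n_total * params$t_machine,
    semi_auto = n_total * params$t_machine + n_reviewed * params$t_human
  )
  cost <- c(
    fully_human = n_total * params$c_human,
    fully_auto = n_total * params$machine_marginal_cost,
    semi_auto = n_reviewed * params$c_human +
      n_total * params$machine_marginal_cost
  )
  strategies <- tibble::tibble(
    strategy = names(time_min),
    total_time_h = unname(time_min) / 60,
    mean_time_min_per_image = unname(time_min) / n_total,
    total_cost = unname(cost),
    mean_cost_per_image = unname(cost) / n_total
  )
  frac <- function(semi, full) if (full == 0) NA_real_ else 1 - semi / full
  mean_t <- setNames(strategies$mean_time_min_per_image, strategies$strategy)
  mean_c <- setNames(strategies$mean_cost_per_image, strategies$strategy)
  out <- list(
    strategies = strategies,
    n_total = n_total, n_reviewed = n_reviewed,
    saving_time_fraction = frac(time_min[["semi_auto"]],
                                time_min[["fully_human"]]),
    saving_cost_fraction = frac(cost[["semi_auto"]], cost[["fully_human"]]),
    saving_time_fraction_printed =
      frac(round(mean_t[["semi_auto"]], round_time_digits),
           round(mean_t[["fully_human"]], round_time_digits + 1)),
    saving_cost_fraction_printed =
      frac(round(mean_c[["semi_auto"]], round_cost_digits),
           round(mean_c[["fully_human"]], round_cost_digits))
  )
  structure(out, class = "dr_cost_report")
}

#' @export
print.dr_cost_report <- function(x, ...) {
  cat("<dr_cost_report> ", x$n_total, " images, ", x$n_reviewed,
      " human-reviewed\n", sep = "")
  print(x$strategies)
  cat(sprintf("time saving vs fully human: %.1f%% (printed-precision: %.1f%%)\n",
              100 * x$saving_time_fraction,
              100 * x$saving_time_fraction_printed))
  cat(sprintf("cost saving vs fully human: %.1f%% (printed-precision: %.1f%%)\n",
              100 * x$saving_cost_fraction,
              100 * x$saving_cost_fraction_printed))
  invisible(x)
}
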
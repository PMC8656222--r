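#' Calibrate a score-generating classifier model to a target AUC
#'
#' Builds the parametric model of the automated grader's continuous output:
#' a latent score distribution conditional on true referable status, mapped
#' to `[0, 1]`, together with an operating threshold. Two families are
#' available:
#'
#' * `"binormal"` — latent score is N(0, 1) for non-referable and N(d, 1)
#'   for referable images; the analytic AUC is \eqn{\Phi(d/\sqrt{2})}, so the
#'   separation solving a target AUC is \eqn{d = \sqrt{2}\,\Phi^{-1}(AUC)}.
#'   Latent scores are mapped to `[0, 1]` by the logistic function.
#' * `"beta"` — scores live natively in `[0, 1]`: Beta(1, k) for
#'   non-referable, Beta(k, 1) for referable, with analytic
#'   \eqn{AUC = 1 - \Gamma(k+1)^2/\Gamma(2k+1)}; k is solved numerically.
#'
#' For the binormal family the logistic mapping is anchored so that the
#' operating threshold on the probability scale corresponds to a chosen
#' latent operating point:
#'
#' * `anchor = "flag_rate"` (default): the latent cutoff is chosen so that
#'   the marginal fraction of images called positive equals `flag_rate` at
#'   true prevalence `prevalence`. This reproduces how a deployed screening
#'   classifier's cutoff manifests: the programme observes its flag rate,
#'   not the latent ROC. At the defaults (AUC 0.953, threshold 0.485,
#'   flag rate 1.45%, prevalence 1.05%) the implied full-cohort operating
#'   point is sensitivity ~0.51, specificity ~0.991.
#' * `anchor = "youden"`: the latent cutoff is the Youden-optimal point
#'   d/2, where sensitivity equals specificity.
#'
#' @param target_auc Target area under the ROC curve, in (0.5, 1).
#' @param family `"binormal"` or `"beta"`.
#' @param threshold Operating threshold on the `[0, 1]` score scale
#'   (default 0.485).
#' @param anchor How the threshold is tied to the latent scale (binormal
#'   family only): `"flag_rate"` or `"youden"`.
#' @param flag_rate,prevalence Marginal positive-call rate and true
#'   referable prevalence used by the `"flag_rate"` anchor.
#' @return An object of class `dr_classifier` with elements `family`,
#'   `auc` (analytic), `threshold`, and family-specific parameters
#'   (`d` and `latent_cutoff` for binormal; `k` for beta).
#' @export
#' @examples
#' m <- calibrate_classifier(0.953)
#' m$d                       # ~2.37
#' m$auc                     # exactly 0.953 analytically
calibrate_classifier <- function(target_auc,
                                 family = c("binormal", "beta"),
                                 threshold = 0.485,
                                 anchor = c("flag_rate", "youden"),
                                 flag_rate = 0.0145,
                                 prevalence = 0.0105) {
  family <- match.arg(family)
  anchor <- match.arg(anchor)
  if (!is.numeric(target_auc) || length(target_auc) != 1L ||
      target_auc < 0.5 || target_auc >= 1) {
    stop("`target_auc` must be a single number in [0.5, 1)", call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }

  if (family == "binormal") {
    d <- sqrt(2) * qnorm(target_auc)
    if (d == 0 || anchor == "youden") {
      latent_cutoff <- d / 2
    } else {
      # marginal flag rate (1-p)*P(X0 > c) + p*P(X1 > c) = flag_rate
      f <- function(c) {
        (1 - prevalence) * pnorm(c, lower.tail = FALSE) +
          prevalence * pnorm(c - d, lower.tail = FALSE) - flag_rate
      }
      latent_cutoff <- uniroot(f, lower = -10, upper = d + 10)$root
    }
    model <- list(family = "binormal", auc = target_auc, d = d,
                  threshold = threshold, latent_cutoff = latent_cutoff)
  } else {
    if (target_auc == 0.5) {
      k <- 1
    } else {
      # AUC(k) = 1 - gamma(k+1)^2 / gamma(2k+1), increasing in k
      f <- function(k) 1 - exp(2 * lgamma(k + 1) - lgamma(2 * k + 1)) - target_auc
      k <- uniroot(f, lower = 1, upper = 1e4, tol = 1e-12)$root
    }
    model <- list(family = "beta", auc = target_auc, k = k,
                  threshold = threshold)
  }
  structure(model, class = "dr_classifier")
}

#' @export
print.dr_classifier <- function(x, ...) {
  cat("<dr_classifier> family:", x$family,
      " analytic AUC:", format(x$auc),
      " threshold:", format(x$threshold), "\n")
  if (x$family == "binormal") {
    cat("  binormal separation d =", format(x$d),
        "; latent cutoff =", format(x$latent_cutoff), "\n")
  } else {
    cat("  beta shape k =", format(x$k), "\n")
  }
  invisible(x)
}

#' Draw classifier scores conditional on referable status
#'
#' Vectorised sampler for the score model built by
#' [calibrate_classifier()]. Scores always lie in `[0, 1]`. Uses the
#' current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param model A `dr_classifier`.
#' @param referable Logical vector of true referable status, one per score.
#' @return Numeric vector of scores in `[0, 1]`, same length as `referable`.
#' @export
draw_scores <- function(model, referable) {
  stopifnot(inherits(model, "dr_classifier"), is.logical(referable))
  n <- length(referable)
  if (model$family == "binormal") {
    latent <- rnorm(n, mean = ifelse(referable, model$d, 0))
    # logistic map anchored so that score == threshold at the latent cutoff
    plogis(latent - model$latent_cutoff + qlogis(model$threshold))
  } else {
    ifelse(referable, rbeta(n, model$k, 1), rbeta(n, 1, model$k))
  }
}
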
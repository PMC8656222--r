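#' Two-by-two confusion matrix of automated decisions against a reference
#'
#' Cross-tabulates automated `POSITIVE`/`NEGATIVE` calls against the
#' reference referable status on a common gradable image set. Ungradable
#' images must be excluded upstream: they enter no accuracy denominator.
#'
#' @param decisions A data frame with `image_id` and `decision`; rows with
#'   decision `UNGRADABLE` are rejected.
#' @param reference A data frame with `image_id` and either a logical
#'   `referable` column or a `grade` column of NHS labels.
#' @return An object of class `dr_confusion` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(decisions, reference) {
  if (!setequal(decisions$image_id, reference$image_id)) {
    stop("`decisions` and `reference` must cover the same image set",
         call. = FALSE)
  }
  if (any(decisions$decision == "UNGRADABLE")) {
    stop("ungradable images must be excluded before computing a confusion ",
         "matrix", call. = FALSE)
  }
  ref <- if ("referable" %in% names(reference)) reference$referable
         else is_referable(reference$grade)
  ref <- ref[match(decisions$image_id, reference$image_id)]
  pos <- decisions$decision == "POSITIVE"
  confusion_matrix(tp = sum(pos & ref), fp = sum(pos & !ref),
                   fn = sum(!pos & ref), tn = sum(!pos & !ref))
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @export
#' @examples
#' cm <- confusion_matrix(tp = 191, fp = 289, fn = 7, tn = 2117)
#' accuracy_sens_spec(cm)
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers",
         call. = FALSE)
  }
  structure(as.list(cells), class = "dr_confusion")
}

#' @export
print.dr_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (tp + tn) / n`, `sensitivity = tp / (tp + fn)`,
#' `specificity = tn / (tn + fp)`. A ratio with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return A named list with `accuracy`, `sensitivity`, `specificity` and
#'   `n`.
#' @export
accuracy_sens_spec <- function(cm) {
  stopifnot(inherits(cm, "dr_confusion"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (cm$tp + cm$tn) / n,
       sensitivity = ratio(cm$tp, cm$tp + cm$fn),
       specificity = ratio(cm$tn, cm$tn + cm$fp),
       n = n)
}

#' Weighted kappa with Cicchetti-Allison (linear) weights
#'
#' Chance-corrected agreement for a k-by-k contingency table of two raters
#' over the same ordinal scale:
#' \deqn{\kappa_W = \frac{\sum w_{ij} p_{ij} - \sum w_{ij} p_{i\cdot} p_{\cdot j}}
#'                       {1 - \sum w_{ij} p_{i\cdot} p_{\cdot j}}}
#' with linear agreement weights \eqn{w_{ij} = 1 - |i - j|/(k - 1)}. For
#' k = 2 this reduces to unweighted Cohen's kappa. The confidence interval
#' uses the large-sample (Fleiss-Cohen-Everitt) standard error for weighted
#' kappa.
#'
#' @param table A square matrix of agreement counts (rows: rater 1,
#'   columns: rater 2, categories in the same order).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `kappa`, `se`, `ci_lower`, `ci_upper`, `weights`,
#'   `n`.
#' @export
#' @examples
#' tab <- matrix(c(191, 7, 289, 2117), 2, 2)  # rows: test, cols: reference
#' weighted_kappa(tab)$kappa  # ~0.511
weighted_kappa <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table) || nrow(table) < 2) {
    stop("`table` must be a square matrix with k >= 2", call. = FALSE)
  }
  if (any(table < 0) || sum(table) == 0) {
    stop("`table` must contain non-negative counts with a positive total",
         call. = FALSE)
  }
  k <- nrow(table)
  n <- sum(table)
  p <- table / n
  w <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  pi_ <- rowSums(p)
  p_j <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, p_j))
  if (pe == 1) {
    # degenerate margins (all mass in one category): agreement is exact
    return(list(kappa = 1, se = 0, ci_lower = 1, ci_upper = 1,
                weights = w, n = n))
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt large-sample variance of weighted kappa
  wi <- as.vector(w %*% p_j)   # expected weight of row category i
  wj <- as.vector(t(w) %*% pi_)
  term <- sum(p * (w - outer(wi, wj, "+") * (1 - kap))^2)
  var_k <- max(0, (term - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2))
  se <- sqrt(var_k)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kap, se = se,
       ci_lower = max(-1, kap - z * se), ci_upper = min(1, kap + z * se),
       weights = w, n = n)
}

#' Empirical ROC curve, AUC, bootstrap CI and Youden-optimal cutoff
#'
#' Builds the empirical ROC over all distinct score thresholds (decision
#' rule: positive iff score >= cutoff) and integrates it by the trapezoidal
#' rule — equivalent to the normalised Mann-Whitney concordance count with
#' ties scored one half. The optimal operating cutoff maximises Youden's
#' J = sensitivity + specificity - 1; among tied maximisers the smallest
#' cutoff is returned (favouring sensitivity, as a screening programme
#' would). The CI is a seeded stratified bootstrap (resampling positives
#' and negatives separately).
#'
#' @param scores Numeric scores.
#' @param referable Logical reference status, same length as `scores`.
#' @param conf_level Confidence level (default 0.95).
#' @param boot Number of bootstrap replicates (default 2000); `0` skips the
#'   CI.
#' @param rng_seed Seed for the bootstrap.
#' @return A list with `auc`, `ci_lower`, `ci_upper`, `cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, and the ROC coordinates as a
#'   tibble `roc` (columns `cutoff`, `fpr`, `tpr`).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.4, 0.8, 0.2), c(TRUE, TRUE, FALSE, FALSE), boot = 0)$auc
roc_auc <- function(scores, referable, conf_level = 0.95, boot = 2000,
                    rng_seed = 1L) {
  stopifnot(length(scores) == length(referable), !anyNA(scores),
            !anyNA(referable))
  n1 <- sum(referable)
  n0 <- sum(!referable)
  if (n1 == 0 || n0 == 0) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  curve <- roc_points(scores, referable)
  auc <- trapezoid_auc(curve$fpr, curve$tpr)

  j <- curve$tpr - curve$fpr
  finite <- is.finite(curve$cutoff)
  best <- which(finite & j >= max(j[finite]) - 1e-12)
  cutoff <- min(curve$cutoff[best])
  at <- which(finite & curve$cutoff == cutoff)[1]

  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    pos <- scores[referable]
    neg <- scores[!referable]
    reps <- with_seed(substream_seed(rng_seed, "auc_bootstrap"),
      vapply(seq_len(boot), function(b) {
        ps <- sample(pos, n1, replace = TRUE)
        ns <- sample(neg, n0, replace = TRUE)
        cv <- roc_points(c(ps, ns), c(rep(TRUE, n1), rep(FALSE, n0)))
        trapezoid_auc(cv$fpr, cv$tpr)
      }, numeric(1)))
    alpha <- 1 - conf_level
    ci <- unname(quantile(reps, c(alpha / 2, 1 - alpha / 2), type = 7))
  }
  list(auc = auc, ci_lower = ci[1], ci_upper = ci[2],
       cutoff = cutoff,
       sens_at_cutoff = curve$tpr[at], spec_at_cutoff = 1 - curve$fpr[at],
       roc = curve)
}

# Empirical ROC coordinates over the distinct cutoffs (rule: score >= c),
# from (0,0) at cutoff +Inf down to (1,1) at the minimum score.
roc_points <- function(scores, referable) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  r <- referable[o]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(r)[last_of_tie]
  fp <- cumsum(!r)[last_of_tie]
  tibble::tibble(
    cutoff = c(Inf, s[last_of_tie]),
    fpr = c(0, fp) / sum(!referable),
    tpr = c(0, tp) / sum(referable)
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Per-year screening summary shaped like a programme report
#'
#' Summarises a workflow run year by year: images included, automated
#' positive/negative/ungradable counts, how many were human-reviewed, how
#' many the humans called positive, and — on the reviewed gradable subset,
#' as a programme evaluating its classifier against the adjudicated
#' reference would — AUC, sensitivity, specificity and accuracy. A pooled
#' row aggregates all years; its AUC is computed both from the pooled
#' reviewed scores (`auc`) and as the unweighted mean of the yearly AUCs
#' (`auc_mean_years`), since the two aggregations answer different
#' questions.
#'
#' @param cohort A `dr_cohort`.
#' @param result A `dr_workflow_result` for that cohort.
#' @param reference_grades Adjudicated grades (from [adjudicate_images()])
#'   for the reviewed images.
#' @param boot Bootstrap replicates for per-year AUC CIs (0 = none,
#'   default, to keep report generation fast).
#' @return A tibble with one row per year plus a pooled row.
#' @export
yearly_report <- function(cohort, result, reference_grades, boot = 0) {
  df <- dplyr::inner_join(
    tibble::as_tibble(cohort)[, c("image_id", "visit_year", "gradable")],
    tibble::as_tibble(result), by = "image_id")
  df$ref_grade <- reference_grades$grade[match(df$image_id,
                                               reference_grades$image_id)]
  one <- function(sub, year_label) {
    rev_mask <- sub$selected & sub$gradable
    rev <- sub[rev_mask & !is.na(sub$ref_grade), ]
    met <- list(auc = NA_real_, sens = NA_real_, spec = NA_real_,
                acc = NA_real_)
    if (nrow(rev) > 0 && length(unique(is_referable(rev$ref_grade))) == 2) {
      cm <- confusion(
        tibble::tibble(image_id = rev$image_id, decision = rev$dla_decision),
        tibble::tibble(image_id = rev$image_id, grade = rev$ref_grade))
      ass <- accuracy_sens_spec(cm)
      sc <- cohort$score[match(rev$image_id, cohort$image_id)]
      ra <- roc_auc(sc, is_referable(rev$ref_grade), boot = boot)
      met <- list(auc = ra$auc, sens = ass$sensitivity,
                  spec = ass$specificity, acc = ass$accuracy)
    }
    tibble::tibble(
      year = year_label,
      included = nrow(sub),
      positive = sum(sub$dla_decision == "POSITIVE"),
      negative = sum(sub$dla_decision == "NEGATIVE"),
      ungradable = sum(sub$dla_decision == "UNGRADABLE"),
      reviewed = sum(rev_mask),
      human_positive = sum(is_referable(sub$ref_grade[rev_mask]), na.rm = TRUE),
      auc = met$auc, sensitivity = met$sens, specificity = met$spec,
      accuracy = met$acc
    )
  }
  years <- sort(unique(df$visit_year))
  rows <- dplyr::bind_rows(lapply(years, function(y)
    one(df[df$visit_year == y, ], as.character(y))))
  pooled <- one(df, "pooled")
  pooled$auc_mean_years <- mean(rows$auc, na.rm = TRUE)
  dplyr::bind_rows(rows, pooled)
}
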
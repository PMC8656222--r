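# Independent oracles, kept deliberately naive so they cannot share code
# paths with the implementation they check.

# AUC as the exhaustive Mann-Whitney concordant-pair count over all
# positive x negative pairs, ties scored one half.
mw_auc_oracle <- function(scores, referable) {
  pos <- scores[referable]
  neg <- scores[!referable]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Cohen's kappa for a 2x2 table from raw proportions, written out longhand.
cohen_kappa_oracle <- function(tab) {
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  p_row1 <- (tab[1, 1] + tab[1, 2]) / n
  p_col1 <- (tab[1, 1] + tab[2, 1]) / n
  pe <- p_row1 * p_col1 + (1 - p_row1) * (1 - p_col1)
  (po - pe) / (1 - pe)
}

# Weighted kappa for any k, computed element by element with explicit loops.
weighted_kappa_oracle <- function(tab) {
  k <- nrow(tab)
  n <- sum(tab)
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- 1 - abs(i - j) / (k - 1)
      po <- po + w * tab[i, j] / n
      pe <- pe + w * sum(tab[i, ]) * sum(tab[, j]) / n^2
    }
  }
  (po - pe) / (1 - pe)
}

# A small single-year cohort plus its automated decisions, reused across
# triage and workflow tests.
make_tiny_run <- function(n_patients = 200, seed = 11, p_ungradable = 0.02,
                          p_referable = 0.08, auc = 0.95) {
  params <- cohort_params(n_patients = n_patients, years = 2009,
                          p_referable_patient = p_referable,
                          p_ungradable = p_ungradable, rng_seed = seed)
  model <- calibrate_classifier(auc, anchor = "youden")
  cohort <- simulate_cohort(params, model)
  list(params = params, model = model, cohort = cohort,
       decisions = dla_decide(cohort, model))
}
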
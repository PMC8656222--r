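test_that("confusion cross-tabulates decisions against the reference", {
  ids <- paste0("i", 1:8)
  dec <- tibble::tibble(image_id = ids,
                        decision = rep(c("POSITIVE", "NEGATIVE"), 4))
  ref_same <- tibble::tibble(image_id = ids,
                             referable = rep(c(TRUE, FALSE), 4))
  cm <- confusion(dec, ref_same)
  expect_equal(c(cm$fp, cm$fn), c(0L, 0L))
  expect_equal(c(cm$tp, cm$tn), c(4L, 4L))
  # complementing the decisions swaps tp<->fn and tn<->fp
  dec_flip <- dec
  dec_flip$decision <- ifelse(dec$decision == "POSITIVE",
                              "NEGATIVE", "POSITIVE")
  cm2 <- confusion(dec_flip, ref_same)
  expect_equal(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn),
               c(cm$fn, cm$tn, cm$tp, cm$fp))
  # mismatched image sets and ungradable rows are consistency errors
  expect_error(confusion(dec[1:4, ], ref_same), "same image set")
  dec$decision[1] <- "UNGRADABLE"
  expect_error(confusion(dec, ref_same), "ungradable")
})

test_that("a reconstructed baseline review set yields the printed metrics", {
  # counts as observed in a 2,604-image reviewed set
  cm <- confusion_matrix(tp = 191, fp = 289, fn = 7, tn = 2117)
  m <- accuracy_sens_spec(cm)
  expect_equal(m$accuracy, 2308 / 2604)
  expect_equal(round(m$accuracy, 3), 0.886)
  expect_equal(m$specificity, 2117 / 2406)
  expect_equal(round(m$specificity, 3), 0.880)
  expect_equal(m$sensitivity, 191 / 198)
  # and via the vector route, rebuilding image-level data from the counts
  ids <- paste0("i", 1:2604)
  dec <- rep(c("POSITIVE", "POSITIVE", "NEGATIVE", "NEGATIVE"),
             c(191, 289, 7, 2117))
  ref <- rep(c(TRUE, FALSE, TRUE, FALSE), c(191, 289, 7, 2117))
  cm2 <- confusion(tibble::tibble(image_id = ids, decision = dec),
                   tibble::tibble(image_id = ids, referable = ref))
  expect_equal(unclass(cm2)[c("tp", "fp", "fn", "tn")],
               list(tp = 191L, fp = 289L, fn = 7L, tn = 2117L))
})

test_that("degenerate confusion matrices are flagged, not zeroed", {
  m <- accuracy_sens_spec(confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  expect_error(accuracy_sens_spec(confusion_matrix(0, 0, 0, 0)), "empty")
  m2 <- accuracy_sens_spec(confusion_matrix(1, 0, 0, 1))
  expect_equal(c(m2$accuracy, m2$sensitivity, m2$specificity), c(1, 1, 1))
})

test_that("weighted kappa reproduces hand-computed agreement", {
  tab <- matrix(c(191, 7, 289, 2117), 2, 2)
  k <- weighted_kappa(tab)
  expect_equal(round(k$kappa, 3), 0.511)
  expect_equal(k$kappa, cohen_kappa_oracle(tab), tolerance = 1e-12)
  # the large-sample CI lands where the asymptotic theory puts it
  expect_equal(c(k$ci_lower, k$ci_upper), c(0.465, 0.557), tolerance = 2e-3)
  # perfect agreement
  expect_equal(weighted_kappa(diag(c(5, 9, 3)))$kappa, 1)
  # chance-only agreement: counts proportional to margin products
  marg <- outer(c(10, 30, 60), c(20, 30, 50))
  expect_equal(weighted_kappa(marg)$kappa, 0, tolerance = 1e-12)
})

test_that("kappa is invariant under scaling the table", {
  set.seed(10)
  for (k_cat in c(2, 3, 5)) {
    tab <- matrix(rpois(k_cat^2, 20) + 1, k_cat, k_cat)
    a <- weighted_kappa(tab)$kappa
    b <- weighted_kappa(tab * 7L)$kappa
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(a, weighted_kappa_oracle(tab), tolerance = 1e-12)
  }
})

test_that("weighted kappa rejects malformed tables", {
  expect_error(weighted_kappa(matrix(1, 2, 3)), "square")
  expect_error(weighted_kappa(matrix(0, 2, 2)), "positive total")
  expect_error(weighted_kappa(matrix(c(1, -1, 0, 2), 2, 2)), "non-negative")
})

test_that("trapezoid AUC equals the exhaustive pair-count oracle", {
  # perfectly separated
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                       boot = 0)$auc, 1)
  # worked 4-point example: 3 concordant pairs of 4
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE), boot = 0)$auc, 3 / 4)
  # random instances with heavy ties
  set.seed(20)
  for (trial in 1:200) {
    n <- sample(4:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    ref <- runif(n) < 0.5
    if (!any(ref) || all(ref)) next
    expect_equal(roc_auc(scores, ref, boot = 0)$auc,
                 mw_auc_oracle(scores, ref), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  ref <- runif(500) < 0.3
  scores <- rnorm(500, mean = ifelse(ref, 1, 0))
  ours <- roc_auc(scores, ref, boot = 0)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(ref, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the Youden cutoff maximises J and breaks ties downward", {
  # J is maximised at any cutoff in (0.4, 0.6]; distinct scores make the
  # smallest maximiser well-defined
  scores <- c(0.9, 0.8, 0.6, 0.3, 0.2, 0.1)
  ref <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- roc_auc(scores, ref, boot = 0)
  expect_equal(r$cutoff, 0.6)
  expect_equal(r$sens_at_cutoff, 1)
  expect_equal(r$spec_at_cutoff, 1)
})

test_that("bootstrap CI brackets the point estimate and is seeded", {
  set.seed(40)
  ref <- rep(c(TRUE, FALSE), c(60, 240))
  scores <- rnorm(300, ifelse(ref, 1.5, 0))
  a <- roc_auc(scores, ref, boot = 200, rng_seed = 9)
  b <- roc_auc(scores, ref, boot = 200, rng_seed = 9)
  expect_identical(a$ci_lower, b$ci_lower)
  expect_lte(a$ci_lower, a$auc)
  expect_gte(a$ci_upper, a$auc)
})

test_that("single-class reference is rejected", {
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE), boot = 0),
               "positive and one negative")
})

test_that("sensitivity and specificity ignore prevalence; accuracy does not", {
  set.seed(50)
  n1 <- 300
  n0 <- 3000
  sens <- 0.8
  spec <- 0.9
  dec_pos <- runif(n1) < sens
  dec_neg <- runif(n0) >= spec
  build <- function(keep_neg) {
    dec <- c(ifelse(dec_pos, "POSITIVE", "NEGATIVE"),
             ifelse(dec_neg[keep_neg], "POSITIVE", "NEGATIVE"))
    ref <- c(rep(TRUE, n1), rep(FALSE, sum(keep_neg)))
    ids <- paste0("i", seq_along(ref))
    accuracy_sens_spec(confusion(
      tibble::tibble(image_id = ids, decision = dec),
      tibble::tibble(image_id = ids, referable = ref)))
  }
  full <- build(rep(TRUE, n0))
  thinned <- build(seq_len(n0) <= n0 / 10)  # drop 90% of negatives
  expect_equal(thinned$sensitivity, full$sensitivity)
  expect_equal(thinned$specificity, full$specificity, tolerance = 0.05)
  expect_false(isTRUE(all.equal(thinned$accuracy, full$accuracy,
                                tolerance = 0.01)))
})

test_that("reviewed-subset specificity is depressed by verification bias", {
  run <- make_tiny_run(n_patients = 1500, seed = 61, p_referable = 0.04)
  sel <- select_for_review(run$cohort, run$decisions,
                           triage_config(qa_fraction = 0.05, rng_seed = 61))
  co <- run$cohort
  gradable <- co[co$gradable, ]
  truth_ref <- tibble::tibble(image_id = gradable$image_id,
                              referable = is_referable(gradable$true_grade))
  dec <- run$decisions[match(gradable$image_id, run$decisions$image_id), ]
  full <- accuracy_sens_spec(confusion(dec, truth_ref))
  rev_ids <- intersect(sel$image_id, gradable$image_id)
  reviewed <- accuracy_sens_spec(confusion(
    dec[dec$image_id %in% rev_ids, ],
    truth_ref[truth_ref$image_id %in% rev_ids, ]))
  # automated negatives are under-sampled in review, so the reviewed frame
  # sees proportionally more false positives among its negatives
  expect_lte(reviewed$specificity, full$specificity)
})
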
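# hand-built cohort rows for rule-level tests
toy_cohort <- function() {
  df <- tibble::tibble(
    image_id = c("a1", "a2", "a3", "b1", "b2"),
    patient_id = c("A", "A", "A", "B", "B"),
    visit_year = 2009L,
    eye = c("left", "left", "right", "left", "left"),
    field = c("F1", "F2", "F1", "F1", "F2"),
    true_grade = c("R2", "R0", "R0", "R0", "R0"),
    gradable = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    score = c(0.9, 0.1, NA, 0.2, 0.3)
  )
  validate_cohort(df)
}

test_that("threshold decision is boundary-inclusive and quality-aware", {
  co <- tibble::tibble(image_id = c("x", "y", "z"),
                       gradable = c(TRUE, FALSE, TRUE),
                       score = c(0.485, NA, 0.2))
  d <- dla_decide(co, calibrate_classifier(0.953, threshold = 0.485))
  expect_equal(d$decision, c("POSITIVE", "UNGRADABLE", "NEGATIVE"))
})

test_that("selection applies the positive / patient-linked / QA rules", {
  co <- toy_cohort()
  d <- tibble::tibble(image_id = co$image_id,
                      decision = c("POSITIVE", "NEGATIVE", "UNGRADABLE",
                                   "NEGATIVE", "NEGATIVE"))
  sel <- select_for_review(co, d, triage_config(qa_fraction = 0))
  expect_setequal(sel$image_id, c("a1", "a2", "a3"))
  expect_equal(sel$reason[match(c("a1", "a2", "a3"), sel$image_id)],
               c("DLA_POSITIVE", "PATIENT_LINKED", "PATIENT_LINKED"))
  # ungradable linked images can be excluded
  sel2 <- select_for_review(co, d, triage_config(
    qa_fraction = 0, include_ungradable_linked = FALSE))
  expect_setequal(sel2$image_id, c("a1", "a2"))
  # no positives -> empty selection at qa_fraction 0
  d_neg <- tibble::tibble(image_id = co$image_id,
                          decision = c("NEGATIVE", "NEGATIVE", "UNGRADABLE",
                                       "NEGATIVE", "NEGATIVE"))
  expect_equal(nrow(select_for_review(co, d_neg,
                                      triage_config(qa_fraction = 0))), 0L)
})

test_that("an image is selected at most once, with reason priority", {
  run <- make_tiny_run(n_patients = 400, seed = 21)
  sel <- select_for_review(run$cohort, run$decisions,
                           triage_config(qa_fraction = 0.05, rng_seed = 21))
  expect_false(anyDuplicated(sel$image_id) > 0)
  d <- run$decisions$decision[match(sel$image_id, run$decisions$image_id)]
  # every positive image is tagged DLA_POSITIVE, never PATIENT_LINKED
  expect_true(all(sel$reason[d == "POSITIVE"] == "DLA_POSITIVE"))
  expect_true(all(d[sel$reason == "QA_SAMPLE"] == "NEGATIVE"))
  # ungradable images are never QA-sampled
  expect_false(any(sel$reason == "QA_SAMPLE" & d == "UNGRADABLE"))
})

test_that("raising the QA fraction never removes an image from selection", {
  run <- make_tiny_run(n_patients = 300, seed = 31)
  fractions <- c(0, 0.02, 0.05, 0.10, 1)
  sels <- lapply(fractions, function(f)
    select_for_review(run$cohort, run$decisions,
                      triage_config(qa_fraction = f, rng_seed = 31)))
  for (i in seq_along(sels)[-1]) {
    expect_true(all(sels[[i - 1]]$image_id %in% sels[[i]]$image_id),
                info = paste("fraction", fractions[i]))
  }
})

test_that("selection is deterministic given the seed", {
  run <- make_tiny_run(n_patients = 300, seed = 41)
  cfg <- triage_config(qa_fraction = 0.05, rng_seed = 5)
  s1 <- select_for_review(run$cohort, run$decisions, cfg)
  s2 <- select_for_review(run$cohort, run$decisions, cfg)
  expect_identical(s1, s2)
})

test_that("review-set accounting composes additively", {
  # a cohort engineered to the baseline component sizes: 480 positives,
  # 624 patient-linked, 1500 QA negatives -> 2,604 reviewed
  n_flagged <- 120
  per_pos <- 4   # 480 positives
  rows <- list()
  for (i in seq_len(n_flagged)) {
    pid <- sprintf("F%03d", i)
    n_link <- if (i <= 24) 6L else 5L  # 24*6 + 96*5 = 624
    ids <- paste0(pid, "_", seq_len(per_pos + n_link))
    rows[[i]] <- tibble::tibble(
      image_id = ids, patient_id = pid, visit_year = 2009L,
      eye = rep(c("left", "right"), length.out = length(ids)),
      field = paste0("F", seq_along(ids)),  # synthetic field labels
      true_grade = "R0", gradable = TRUE,
      score = c(rep(0.9, per_pos), rep(0.1, n_link)))
  }
  clean <- tibble::tibble(
    image_id = paste0("N", 1:30000), patient_id = paste0("C", 1:30000),
    visit_year = 2009L, eye = "left", field = "F1",
    true_grade = "R0", gradable = TRUE, score = 0.1)
  co <- dplyr::bind_rows(dplyr::bind_rows(rows), clean)
  d <- dla_decide(co, 0.485)
  sel <- select_for_review(co, d, triage_config(qa_count_override = 1500,
                                                rng_seed = 1))
  expect_equal(unname(table(sel$reason)[c("DLA_POSITIVE", "PATIENT_LINKED",
                                          "QA_SAMPLE")]),
               c(480L, 624L, 1500L), ignore_attr = TRUE)
  expect_equal(nrow(sel), 2604L)
})

test_that("QA override larger than the negative pool is an error", {
  co <- toy_cohort()
  d <- dla_decide(co, 0.485)
  expect_error(select_for_review(co, d,
                                 triage_config(qa_count_override = 10000)),
               "negative pool")
})

test_that("final labels pass through or take the human reference", {
  co <- toy_cohort()
  d <- tibble::tibble(image_id = co$image_id,
                      decision = c("POSITIVE", "NEGATIVE", "UNGRADABLE",
                                   "NEGATIVE", "NEGATIVE"))
  sel <- select_for_review(co, d, triage_config(qa_fraction = 0))
  # perfect graders: a1 is a DLA call on a truly referable image, a2 truth R0
  ref <- tibble::tibble(image_id = c("a1", "a2"), grade = c("R2", "R0"))
  res <- assemble_workflow_result(co, d, sel, ref)
  expect_equal(res$final_label[res$image_id == "a1"], "POSITIVE")
  expect_equal(res$label_source[res$image_id == "a1"], "HUMAN")
  # unselected negative passes through with its automated label
  expect_equal(res$final_label[res$image_id == "b1"], "NEGATIVE")
  expect_equal(res$label_source[res$image_id == "b1"], "DLA")
  # ungradable selected image stays ungradable (no human grade possible)
  expect_equal(res$final_label[res$image_id == "a3"], "UNGRADABLE")
  # partition: final labels count up to the cohort size
  expect_equal(sum(table(res$final_label)), nrow(co))
})

test_that("a reviewed DLA false positive is corrected by perfect graders", {
  co <- validate_cohort(tibble::tibble(
    image_id = "fp1", patient_id = "Z", visit_year = 2009L, eye = "left",
    field = "F1", true_grade = "R0", gradable = TRUE, score = 0.99))
  d <- dla_decide(co, 0.485)
  sel <- select_for_review(co, d, triage_config(qa_fraction = 0))
  ref <- adjudicate_images(co, adjudication_config(
    panel = list(grader_profile("G1", 1, 1)), rng_seed = 1))
  res <- assemble_workflow_result(co, d, sel, ref)
  expect_equal(res$final_label, "NEGATIVE")
  expect_equal(res$label_source, "HUMAN")
})

test_that("a missing reference grade for a selected image is an error", {
  co <- toy_cohort()
  d <- tibble::tibble(image_id = co$image_id,
                      decision = c("POSITIVE", "NEGATIVE", "UNGRADABLE",
                                   "NEGATIVE", "NEGATIVE"))
  sel <- select_for_review(co, d, triage_config(qa_fraction = 0))
  ref <- tibble::tibble(image_id = "a1", grade = "R2")  # a2 missing
  expect_error(assemble_workflow_result(co, d, sel, ref),
               "missing reference")
})

test_that("full review with perfect graders recovers truth exactly", {
  run <- make_tiny_run(n_patients = 50, seed = 51)
  sel <- select_for_review(run$cohort, run$decisions,
                           triage_config(qa_fraction = 1, rng_seed = 51))
  gradable_sel <- run$cohort[run$cohort$image_id %in% sel$image_id &
                               run$cohort$gradable, ]
  ref <- adjudicate_images(gradable_sel, adjudication_config(
    panel = list(grader_profile("G1", 1, 1)), rng_seed = 1))
  res <- assemble_workflow_result(run$cohort, run$decisions, sel, ref)
  gradable <- run$cohort$gradable
  truth_pos <- is_referable(run$cohort$true_grade) & gradable
  # every gradable positive image was either flagged or QA-reviewed
  final_pos <- res$final_label == "POSITIVE"
  expect_identical(final_pos[gradable], truth_pos[gradable])
})
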
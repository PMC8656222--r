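#' Automated grading decision for each image
#'
#' Applies the classifier's operating threshold: an ungradable image is
#' `UNGRADABLE`; otherwise `POSITIVE` iff `score >= threshold` (the
#' boundary counts as positive, fixed for determinism), else `NEGATIVE`.
#'
#' @param cohort A `dr_cohort` (or any data frame with `image_id`,
#'   `gradable`, `score`).
#' @param model A `dr_classifier` supplying the threshold, or a single
#'   numeric threshold.
#' @return A tibble with columns `image_id` and `decision`
#'   (`POSITIVE`/`NEGATIVE`/`UNGRADABLE`).
#' @export
dla_decide <- function(cohort, model) {
  threshold <- if (inherits(model, "dr_classifier")) model$threshold else model
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  decision <- ifelse(!cohort$gradable, "UNGRADABLE",
                     ifelse(cohort$score >= threshold, "POSITIVE", "NEGATIVE"))
  tibble::tibble(image_id = cohort$image_id, decision = decision)
}

#' Configuration of the human-review selection step
#'
#' @param qa_fraction Fraction of the remaining automated-negative pool to
#'   sample for quality assurance (default 0.05, i.e. the "approximately
#'   5% of images randomly sampled" audit).
#' @param qa_count_override Optional fixed QA sample size, overriding
#'   `qa_fraction` (screening programmes often fix a round number, e.g.
#'   1,500, rather than an exact percentage).
#' @param include_ungradable_linked Logical: pull a flagged patient's
#'   ungradable images into the review set too (default `TRUE`).
#' @param link_scope `"visit"` (default) links the other images a flagged
#'   patient contributed to the *same screening round* — the scope under
#'   which one flagged patient-visit contributes exactly its 2 eyes x 2
#'   fields to review; `"all"` links every image of that patient across
#'   years.
#' @param rng_seed Seed for the QA draw.
#' @return An object of class `dr_triage_config`.
#' @export
triage_config <- function(qa_fraction = 0.05, qa_count_override = NULL,
                          include_ungradable_linked = TRUE,
                          link_scope = c("visit", "all"), rng_seed = 1L) {
  link_scope <- match.arg(link_scope)
  if (!is.numeric(qa_fraction) || qa_fraction < 0 || qa_fraction > 1) {
    stop("`qa_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(qa_count_override) &&
      (qa_count_override < 0 || qa_count_override != round(qa_count_override))) {
    stop("`qa_count_override` must be a non-negative integer", call. = FALSE)
  }
  structure(list(qa_fraction = qa_fraction,
                 qa_count_override = qa_count_override,
                 include_ungradable_linked = isTRUE(include_ungradable_linked),
                 link_scope = link_scope,
                 rng_seed = as.integer(rng_seed)),
            class = "dr_triage_config")
}

#' Select images for human regrading
#'
#' Implements the two-step triage rule: (1) every automated-positive image;
#' (2) all other available images from any patient with at least one
#' positive image — including negatives and, if configured, ungradable
#' images; by default linkage is scoped to the same screening round (see
#' [triage_config()]); (3) a seeded simple random sample without
#' replacement of the remaining automated-negative images (the QA audit).
#' Reasons are assigned with priority
#' `DLA_POSITIVE > PATIENT_LINKED > QA_SAMPLE`, so each image appears at
#' most once.
#'
#' @param cohort A `dr_cohort`.
#' @param decisions Output of [dla_decide()] covering every image.
#' @param cfg A [triage_config()].
#' @return A tibble with columns `image_id` and `reason`.
#' @export
select_for_review <- function(cohort, decisions, cfg = triage_config()) {
  stopifnot(inherits(cfg, "dr_triage_config"))
  if (!setequal(decisions$image_id, cohort$image_id)) {
    stop("`decisions` must cover exactly the cohort's images", call. = FALSE)
  }
  d <- decisions$decision[match(cohort$image_id, decisions$image_id)]

  pos_ids <- cohort$image_id[d == "POSITIVE"]
  link_key <- if (cfg$link_scope == "visit") {
    paste(cohort$patient_id, cohort$visit_year)
  } else {
    cohort$patient_id
  }
  flagged <- unique(link_key[d == "POSITIVE"])

  linked_mask <- link_key %in% flagged & d != "POSITIVE"
  if (!cfg$include_ungradable_linked) {
    linked_mask <- linked_mask & d != "UNGRADABLE"
  }
  linked_ids <- cohort$image_id[linked_mask]

  qa_pool <- cohort$image_id[d == "NEGATIVE" &
                               !(cohort$image_id %in% linked_ids)]
  n_qa <- if (!is.null(cfg$qa_count_override)) {
    if (cfg$qa_count_override > length(qa_pool)) {
      stop("`qa_count_override` exceeds the negative pool (",
           length(qa_pool), ")", call. = FALSE)
    }
    cfg$qa_count_override
  } else {
    round(cfg$qa_fraction * length(qa_pool))
  }
  qa_ids <- with_seed(substream_seed(cfg$rng_seed, "qa_sampling"),
                      sample(qa_pool, n_qa))

  tibble::tibble(
    image_id = c(pos_ids, linked_ids, qa_ids),
    reason = rep(c("DLA_POSITIVE", "PATIENT_LINKED", "QA_SAMPLE"),
                 c(length(pos_ids), length(linked_ids), length(qa_ids)))
  )
}

#' Assemble final workflow labels
#'
#' Selected gradable images take their final label from the adjudicated
#' human reference (`POSITIVE` iff the reference grade is referable); every
#' other image keeps its automated decision. `label_source` records which
#' arm produced each label.
#'
#' @param cohort A `dr_cohort`.
#' @param decisions Output of [dla_decide()].
#' @param selection Output of [select_for_review()].
#' @param reference_grades A data frame with `image_id` and `grade` (e.g.
#'   from [adjudicate_images()]), covering every selected gradable image.
#' @return A tibble of class `dr_workflow_result` with per-image columns
#'   `image_id`, `dla_decision`, `selected`, `reason`, `reference_grade`,
#'   `final_label`, `label_source`.
#' @export
assemble_workflow_result <- function(cohort, decisions, selection,
                                     reference_grades) {
  d <- decisions$decision[match(cohort$image_id, decisions$image_id)]
  sel_idx <- match(cohort$image_id, selection$image_id)
  selected <- !is.na(sel_idx)
  reason <- selection$reason[sel_idx]

  ref <- reference_grades$grade[match(cohort$image_id,
                                      reference_grades$image_id)]
  need_ref <- selected & cohort$gradable
  if (any(need_ref & is.na(ref))) {
    stop("missing reference grade for ",
         sum(need_ref & is.na(ref)), " selected gradable image(s)",
         call. = FALSE)
  }

  final <- d
  final[need_ref] <- ifelse(is_referable(ref[need_ref]),
                            "POSITIVE", "NEGATIVE")
  out <- tibble::tibble(
    image_id = cohort$image_id,
    dla_decision = d,
    selected = selected,
    reason = reason,
    reference_grade = ifelse(need_ref, ref, NA_character_),
    final_label = final,
    label_source = ifelse(need_ref, "HUMAN", "DLA")
  )
  class(out) <- c("dr_workflow_result", class(out))
  out
}

#' @export
print.dr_workflow_result <- function(x, ...) {
  tab <- table(x$final_label)
  cat("<dr_workflow_result> ", nrow(x), " images; final labels: ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "; human-reviewed: ", sum(x$label_source == "HUMAN"), "\n", sep = "")
  NextMethod()
}
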
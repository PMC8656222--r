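#' Bundle a full workflow run configuration
#'
#' One global seed deterministically derives every substream seed (cohort
#' truth/quality/scores, QA sampling, grader draws), so re-running with the
#' same configuration is bit-identical while individual components can be
#' varied independently.
#'
#' @param cohort A [cohort_params()].
#' @param classifier A [calibrate_classifier()] model.
#' @param triage A [triage_config()].
#' @param adjudication An [adjudication_config()].
#' @param cost A [cost_params()].
#' @param seed Global integer seed.
#' @return An object of class `dr_run_config`.
#' @export
run_config <- function(cohort,
                       classifier = calibrate_classifier(0.953),
                       triage = triage_config(),
                       adjudication = adjudication_config(),
                       cost = cost_params(),
                       seed = 1L) {
  stopifnot(inherits(cohort, "dr_cohort_params"),
            inherits(classifier, "dr_classifier"),
            inherits(triage, "dr_triage_config"),
            inherits(adjudication, "dr_adjudication_config"),
            inherits(cost, "dr_cost_params"))
  cohort$rng_seed <- substream_seed(seed, "cohort")
  triage$rng_seed <- substream_seed(seed, "triage")
  adjudication$rng_seed <- substream_seed(seed, "adjudication")
  structure(list(cohort = cohort, classifier = classifier, triage = triage,
                 adjudication = adjudication, cost = cost,
                 seed = as.integer(seed)),
            class = "dr_run_config")
}

#' Run the full semi-automated screening workflow
#'
#' Orchestrates simulate -> automated decisions -> review selection ->
#' panel adjudication -> final labels -> accuracy metrics -> cost report.
#' When `out_dir` is given, emits the cohort CSV (+ YAML parameter
#' sidecar), selection CSV, reference CSV, workflow-result CSV, a metrics
#' JSON, a per-year report CSV (one row per simulated year plus a pooled
#' row, metrics rounded to 3 decimals), a cost CSV and a run manifest
#' (configuration, seed, package version).
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list with elements `cohort`, `decisions`,
#'   `selection`, `reference`, `result`, `yearly`, `metrics`,
#'   `cost_report` and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "dr_run_config"))
  cohort <- simulate_cohort(cfg$cohort, cfg$classifier)
  decisions <- dla_decide(cohort, cfg$classifier)
  selection <- select_for_review(cohort, decisions, cfg$triage)

  sel_gradable <- cohort[cohort$image_id %in% selection$image_id &
                           cohort$gradable, ]
  reference <- adjudicate_images(sel_gradable, cfg$adjudication)
  result <- assemble_workflow_result(cohort, decisions, selection, reference)
  yearly <- yearly_report(cohort, result, reference)
  metrics <- workflow_metrics(cohort, result, reference)
  n_reviewed <- sum(result$label_source == "HUMAN")
  cost_report <- cost_evaluate(nrow(cohort), n_reviewed, cfg$cost)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    readr::write_csv(selection, file.path(out_dir, "selection.csv"),
                     progress = FALSE)
    readr::write_csv(reference, file.path(out_dir, "reference.csv"),
                     progress = FALSE)
    readr::write_csv(as.data.frame(result),
                     file.path(out_dir, "workflow.csv"), progress = FALSE)
    yearly_out <- yearly
    num <- vapply(yearly_out, is.double, logical(1))
    yearly_out[num] <- lapply(yearly_out[num], round, digits = 3)
    readr::write_csv(yearly_out, file.path(out_dir, "yearly_report.csv"),
                     progress = FALSE)
    readr::write_csv(cost_report$strategies, file.path(out_dir, "cost.csv"),
                     progress = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(config = config_to_list(cfg),
                     seed = cfg$seed,
                     package_version = as.character(packageVersion("retriage")))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"),
                     precision = 17)
  }
  invisible(list(cohort = cohort, decisions = decisions,
                 selection = selection, reference = reference,
                 result = result, yearly = yearly, metrics = metrics,
                 cost_report = cost_report, out_dir = out_dir))
}

#' Accuracy metrics of a workflow run
#'
#' Two evaluation frames: `reviewed` compares the automated decisions
#' against the adjudicated human reference on the reviewed gradable subset
#' (the frame a real programme can observe — subject to verification bias,
#' since automated negatives are under-sampled), and `full` compares them
#' against the simulated ground truth on every gradable image (the frame
#' only a simulation can observe).
#'
#' @param cohort A `dr_cohort`.
#' @param result A `dr_workflow_result`.
#' @param reference Adjudicated grades from [adjudicate_images()].
#' @return A list with components `reviewed` and `full`, each holding the
#'   confusion cells, accuracy/sensitivity/specificity, AUC with bootstrap
#'   CI and Youden cutoff, and (reviewed frame) weighted kappa with CI.
#' @export
workflow_metrics <- function(cohort, result, reference) {
  frame_metrics <- function(ids, ref_referable) {
    sub <- result[match(ids, result$image_id), ]
    cm <- confusion(
      tibble::tibble(image_id = ids, decision = sub$dla_decision),
      tibble::tibble(image_id = ids, referable = ref_referable))
    ass <- accuracy_sens_spec(cm)
    sc <- cohort$score[match(ids, cohort$image_id)]
    ra <- tryCatch(roc_auc(sc, ref_referable, boot = 500),
                   error = function(e) NULL)
    tab <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2)
    kap <- weighted_kappa(tab)
    list(n = ass$n, tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
         accuracy = ass$accuracy, sensitivity = ass$sensitivity,
         specificity = ass$specificity,
         auc = if (is.null(ra)) NA_real_ else ra$auc,
         auc_ci_lower = if (is.null(ra)) NA_real_ else ra$ci_lower,
         auc_ci_upper = if (is.null(ra)) NA_real_ else ra$ci_upper,
         cutoff = if (is.null(ra)) NA_real_ else ra$cutoff,
         kappa = kap$kappa, kappa_ci_lower = kap$ci_lower,
         kappa_ci_upper = kap$ci_upper)
  }
  rev_ids <- reference$image_id
  reviewed <- frame_metrics(rev_ids, is_referable(reference$grade))
  grad <- cohort[cohort$gradable, ]
  full <- frame_metrics(grad$image_id, is_referable(grad$true_grade))
  list(reviewed = reviewed, full = full)
}

config_to_list <- function(cfg) {
  list(
    cohort = params_to_list(cfg$cohort),
    classifier = unclass(cfg$classifier),
    triage = unclass(cfg$triage),
    adjudication = list(
      panel = lapply(cfg$adjudication$panel, unclass),
      senior = unclass(cfg$adjudication$senior),
      rng_seed = cfg$adjudication$rng_seed
    ),
    cost = unclass(cfg$cost),
    seed = cfg$seed
  )
}

#' Rebuild a run configuration from its manifest serialisation
#'
#' Inverse of the manifest written by [run_pipeline()]: loading the
#' manifest and re-running reproduces the identical run.
#'
#' @param x A list as stored under `config` in `manifest.yaml`, or a path
#'   to a manifest YAML file.
#' @return A `dr_run_config`.
#' @export
run_config_from_list <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)$config
  co <- x$cohort
  co$severity_probs <- unlist(co$severity_probs)
  co$p_ungradable <- unlist(co$p_ungradable)
  co$attendance <- unlist(co$attendance)
  co$years <- unlist(co$years)
  cl <- x$classifier
  model <- calibrate_classifier(cl$auc, family = cl$family,
                                threshold = cl$threshold)
  if (!is.null(cl$latent_cutoff)) model$latent_cutoff <- cl$latent_cutoff
  mk_grader <- function(g) grader_profile(g$grader_id, g$sens_h, g$spec_h,
                                          g$is_senior)
  run_config(
    cohort = do.call(cohort_params, co),
    classifier = model,
    triage = do.call(triage_config, x$triage),
    adjudication = adjudication_config(
      panel = lapply(x$adjudication$panel, mk_grader),
      senior = mk_grader(x$adjudication$senior),
      rng_seed = x$adjudication$rng_seed),
    cost = do.call(cost_params, x$cost),
    seed = x$seed
  )
}
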
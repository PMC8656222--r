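# retriage

Simulation and evaluation toolkit for **semi-automated triage workflows in
diabetic retinopathy (DR) screening**.

Population screening programmes photograph two fields per eye (disc-centred
F1, macula-centred F2) of every attendee and must decide which images show
*referable* DR — NHS grades R2 (pre-proliferative), R3a (active
proliferative) or R3s (stable treated proliferative). Grading everything by
hand is accurate but expensive; automated classifiers are cheap but not
specific enough to act alone at ~1% prevalence. The workflow this package
implements splits the difference:

1. an automated classifier grades every image **positive / negative /
   ungradable** at an operating threshold on its probability score;
2. humans regrade only a high-risk subset: every automated positive, all
   other images from the same patient's screening visit, and a ~5% random
   quality-assurance (QA) sample of the remaining negatives;
3. a grader panel adjudicates the reference standard — unanimous agreement
   on referable status stands, otherwise a senior ophthalmologist's
   reading is conclusive.

The package provides, as testable components:

- a **seeded synthetic-cohort generator** (`simulate_cohort()`) emulating a
  longitudinal two-field screening programme (annual visits, declining
  attendance, ~1% image-level referable prevalence, 2–7% ungradable
  images), with a score model calibrated analytically to a target AUC —
  binormal family: `d = √2·Φ⁻¹(AUC)`, scores mapped to [0,1];
- the **triage engine** (`dla_decide()`, `select_for_review()`,
  `assemble_workflow_result()`) with reason priority
  `DLA_POSITIVE > PATIENT_LINKED > QA_SAMPLE`;
- **panel adjudication** (`adjudicate_images()`) with consensus/senior
  paths;
- the **diagnostic-accuracy layer** (`confusion()`,
  `accuracy_sens_spec()`, `roc_auc()`, `weighted_kappa()`): empirical
  trapezoid ROC/AUC (≡ Mann–Whitney with ties at ½) with stratified
  bootstrap CI and Youden-optimal cutoff, and Cicchetti–Allison weighted
  kappa `κ_W = (Σw·p_obs − Σw·p_exp)/(1 − Σw·p_exp)`, linear weights
  `w_ij = 1 − |i−j|/(k−1)`, with the large-sample Fleiss–Cohen–Everitt CI;
- a **cost model** (`cost_evaluate()`) comparing fully-human,
  fully-automated and semi-automated grading in time and money;
- the **image normalisation chain** (`preprocess()`): 90% centre crop →
  299×299 bilinear resize → Gaussian local-average colour subtraction
  mapped to 50% gray;
- an **orchestrator** (`run_pipeline()`) emitting CSV/JSON/YAML artifacts
  with bit-identical reruns, plus a thin CLI wrapper in
  `inst/scripts/triagescreen.R`.

## Worked example

```r
library(retriage)

cfg <- run_config(
  cohort     = annual_screening_params(n_patients = 2000),  # 8 annual visits
  classifier = calibrate_classifier(0.953),             # threshold 0.485
  triage     = triage_config(qa_fraction = 0.05),
  seed       = 7)
out <- run_pipeline(cfg)

out$cohort
#> <dr_cohort> 43300 images, 2000 patients, years 2009-2017;
#>   ungradable 1814 (4.19%), referable 440 (1.02%)

table(out$decisions$decision)
#>   NEGATIVE   POSITIVE UNGRADABLE
#>      40906        580       1814

table(out$selection$reason)
#>   DLA_POSITIVE PATIENT_LINKED      QA_SAMPLE
#>            580           1512           1973
```

The classifier flags 1.34% of images; with patient linkage and the QA
audit, humans review ~9% of the workload. The two evaluation frames make
verification bias visible:

```r
m <- out$metrics
# reviewed frame: n=3993 acc=0.880 sens=0.657 spec=0.899 auc=0.924 kappa=0.404
# full frame:     n=41486 acc=0.986 sens=0.502 spec=0.991 auc=0.953
```

On the reviewed subset — all a real programme can observe — specificity is
depressed (0.899 vs 0.991) because true negatives enter review only through
the 5% QA sample, while sensitivity is inflated (0.657 vs 0.502) because
most missed cases are never reviewed. The full-cohort AUC recovers the
calibrated 0.953 exactly.

```r
cost_evaluate(nrow(out$cohort), sum(out$result$label_source == "HUMAN"))
#> <dr_cost_report> 43300 images, 3993 human-reviewed
#>   strategy    total_time_h mean_time_min_per_image total_cost mean_cost_per_image
#> 1 fully_human       266.                    0.368      7448.               0.172
#> 2 fully_auto         41.9                   0.058         0                0
#> 3 semi_auto          66.3                   0.0919      687.               0.0159
#> time saving vs fully human: 75.0% (printed-precision: 75.5%)
#> cost saving vs fully human: 90.8% (printed-precision: 90.7%)
```

Agreement statistics work on any square table; on the canonical baseline
review-set confusion matrix:

```r
k <- weighted_kappa(matrix(c(191, 7, 289, 2117), 2, 2))
sprintf("kappa %.3f (%.3f-%.3f)", k$kappa, k$ci_lower, k$ci_upper)
#> "kappa 0.511 (0.465-0.557)"
```

See `vignettes/semiautomated-triage.Rmd` for the models, their assumptions
and the design decisions.

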
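Package: retriage
Title: Semi-Automated Triage Workflows for Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for semi-automated (algorithm
    plus human) grading workflows in diabetic retinopathy screening
    programmes. Generates seeded longitudinal screening cohorts with an
    imperfect automated classifier and imperfect human graders; runs the
    two-step triage protocol (automated grading of every image, then human
    regrading of automated positives, patient-linked images, and a random
    quality-assurance sample of negatives); adjudicates a reference standard
    via a grader panel with senior tie-break; computes diagnostic-accuracy
    statistics (sensitivity, specificity, accuracy, empirical ROC/AUC with
    Youden cutoff, Cicchetti-Allison weighted kappa with asymptotic
    confidence interval); and models the time and monetary cost of fully
    human, fully automated, and semi-automated grading strategies. Includes
    the fundus-photograph normalisation chain (centre crop, resize, local
    average colour subtraction) used to feed such classifiers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
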
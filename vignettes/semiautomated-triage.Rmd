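---
title: "Semi-automated triage for retinopathy screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated triage for retinopathy screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retriage)
```

## The problem

Population screening for diabetic retinopathy (DR) photographs both eyes of
every attendee — a disc-centred (F1) and a macula-centred (F2) field per eye
— and asks whether any image shows *referable* disease: NHS grades R2
(pre-proliferative), R3a (active proliferative) or R3s (stable treated
proliferative). Human grading of every image is accurate but slow and
expensive; automated classifiers are fast and cheap but, at the specificity
a general-population programme needs, not yet trustworthy on their own.

`retriage` implements and evaluates the compromise: a **two-step
semi-automated workflow**. An automated classifier first grades every image
as positive, negative or ungradable. Humans then regrade only a high-risk
subset: every automated positive, *all other images from any patient with a
positive image* (including their negatives and ungradables), and a random
quality-assurance (QA) sample — about 5% — of the remaining negatives. A
grader panel with senior tie-break adjudicates the reference standard on the
reviewed subset. Because no suitable image set is publicly available, the
package pairs the workflow with a seeded synthetic-cohort generator, so
every stage is testable end to end.

## The synthetic cohort

`cohort_params()` / `simulate_cohort()` generate one row per photograph:
2 eyes × 2 fields per attended patient-year, with both fields of an eye-year
sharing one true grade (disease status is an eye property; graders see two
views of the same retina).

The truth model is deliberately minimal:

* Each eye is independently ever-affected with probability
  $1-\sqrt{1-p}$, where $p$ = `p_referable_patient`, so the probability
  that a *patient* is ever affected equals $p$.
* An affected eye has a uniformly distributed onset year; with
  `progression = TRUE` (default) it stays referable afterwards —
  vision-threatening DR does not spontaneously regress on the timescale of
  annual screening. The toggle exists to test the monotonicity machinery.
* Referable eye-years are R2/R3a/R3s with probabilities 0.85/0.10/0.05
  (pre-proliferative disease dominates incident referable DR);
  non-referable eye-years are R1 with probability 0.10, else R0.
* Ungradability is an independent per-image Bernoulli event (default
  2.23%). Whether poor-quality images are *more* likely in diseased eyes
  is unknown; independence is the default and an odds-ratio knob
  (`ungradable_referable_or`) supports sensitivity analyses.

`annual_screening_params()` bundles the conditions of an annual
government-employee screening programme: 4,900 patients, a 2009 baseline
plus 2011–2017 follow-up with attendance declining from 72% to 53%,
per-year ungradable fractions between 2.2% and 7.1%, and
`p_referable_patient = 0.04`, which by the closed form in
`expected_referable_fraction()` puts the image-level referable fraction
near 1% — the low prevalence that makes general-population triage hard.

What the generator does **not** emulate: correlation between fellow eyes,
grade-severity progression within an eye, diabetes incidence or systemic
covariates, camera physics, or any pixel-level structure. Passing tests
therefore certify the workflow logic and statistics, not classifier
performance on real retinas.

## The classifier model and its calibration

Scores are generated conditional on referable status. The default
**binormal** family puts the latent score at $N(0,1)$ for non-referable and
$N(d,1)$ for referable images, so the analytic AUC is $\Phi(d/\sqrt 2)$ and
`calibrate_classifier(auc)` inverts it: $d=\sqrt 2\,\Phi^{-1}(auc)$
(≈ 2.37 at AUC 0.953). The latent score is mapped to $[0,1]$ by the
logistic function; a **beta** family (Beta$(1,k)$ vs Beta$(k,1)$, analytic
AUC $1-\Gamma(k{+}1)^2/\Gamma(2k{+}1)$) is offered because probability
outputs live in $[0,1]$ natively.

The operating threshold defaults to 0.485. How that probability maps onto
the latent scale is a genuine design choice, and we anchor it to the
**deployed flag rate** rather than to the Youden point. The reasoning: a
programme-level report states two facts about its classifier — the review
AUC (~0.95) and the fraction of images it flags (~1.3–1.7% at ~1%
prevalence). Under an equal-variance binormal model those two facts *fix*
the full-cohort operating point at roughly sensitivity 0.51 / specificity
0.991, and they reproduce the observed review-set anatomy (≈480 flags of
which ≈190 true, ≈7 missed cases in a 1,500-image QA sample). The much
higher sensitivity such programmes report on their *reviewed subset* is a
verification-bias artefact (below), not a property of the classifier. A
`"youden"` anchor (sensitivity = specificity at the cutoff) remains
available for conventional ROC work.

## Reference-standard adjudication

Each selected gradable image is read independently by every panel member
(default three trained graders, sensitivity 0.90 / specificity 0.95 each,
grading independently given truth). If all agree on *referable status* the
consensus stands — consensus is defined on the binary endpoint, not the
exact R-category, because the endpoint of the workflow is binary; the
reported category is the panel's modal label, ties broken towards the more
severe grade (screening errs on the side of referral). On any
disagreement a senior ophthalmologist's reading is conclusive. The default
senior is error-free: the workflow treats the senior's diagnosis as the
reference standard by definition, and a fallible senior is a configuration,
not the default. With per-grader accuracy $q$ on a class, the reference is
correct unless the panel is unanimously wrong: $P(\text{correct}) =
1-(1-q)^k$, a bound the test-suite verifies by simulation.

## Accuracy metrics

* **Confusion matrix, accuracy, sensitivity, specificity** — computed on
  gradable images only (an ungradable image has no grade to be right or
  wrong about); zero-denominator ratios are reported as `NA`, never 0.
* **Weighted kappa** — Cicchetti–Allison (linear) weights
  $w_{ij}=1-|i-j|/(k-1)$; for the binary endpoint ($k=2$) this is exactly
  unweighted Cohen's kappa. The CI uses the large-sample
  Fleiss–Cohen–Everitt variance; on the canonical baseline review-set
  table it yields (0.465, 0.557) around κ = 0.511.
* **ROC/AUC** — the empirical ROC over all distinct cutoffs (positive iff
  score ≥ cutoff; the boundary counts as positive, fixed for determinism),
  integrated by the trapezoidal rule. This equals the normalised
  Mann–Whitney concordance count with ties scored ½; the test suite
  asserts that equivalence exactly against a brute-force pair-count oracle
  and against an independent ROC implementation. The Youden-optimal cutoff
  maximises $J = \text{sens}+\text{spec}-1$; among tied maximisers the
  *smallest* cutoff is returned, favouring sensitivity as a screening
  programme would. The AUC CI is a seeded stratified bootstrap (default
  2,000 replicates; the asymptotic DeLong variance is deliberately out of
  scope for this version).

### Verification bias

The workflow can only adjudicate images it reviews, and it reviews
automated positives preferentially. Negatives enter the reviewed frame
mainly through the small QA sample, so false positives are fully
represented there while true negatives are represented at ~5%. Reviewed-
subset specificity is therefore *biased downward* relative to the full
cohort (≈0.88 vs ≈0.99 in the calibrated simulation), and reviewed-subset
sensitivity is biased upward (missed cases surface only via QA and
linkage). `workflow_metrics()` reports both frames — `reviewed`, which a
real programme can observe, and `full`, which only a simulation can — and
the property suite asserts the direction of the bias.

## The cost model

`cost_evaluate(n_total, n_reviewed, params)` compares three strategies with
plain linear arithmetic: fully human ($n_{total} \cdot t_h$ minutes,
$n_{total} \cdot c_h$ currency), fully automated ($n_{total} \cdot t_m$;
machine marginal cost defaults to 0, as grader pay dwarfs inference cost),
and semi-automated (machine over all images, humans over the reviewed
subset). Saving fractions are $1-\text{semi}/\text{fully human}$ per
dimension, reported twice: at full precision, and after rounding the
per-image means to report precision (minutes to 2 decimals, currency to 3).
The second form exists because headline percentages in programme reports
are computed from printed rounded figures — at the default follow-up
workload the canonical time saving is 74.2% while the printed-precision
reproduction gives 75.5% — and the package makes both explicit rather than
leaving the discrepancy to confuse a reader. Totals and means carry full
precision internally; rounding happens only at report emission.

## Determinism and numerical choices

* One global seed per run; every stochastic component (truth, quality,
  scores, QA sampling, grader draws) uses a named substream derived by
  `substream_seed()`, so perturbing one component leaves the others'
  draws untouched. Re-running a configuration is bit-identical, and the
  run manifest (`manifest.yaml`) round-trips into an identical run.
* QA sampling is a simple random sample *without* replacement from the
  post-linkage negative pool: negatives already pulled in by patient
  linkage are not re-sampled, and ungradable images are never QA-sampled
  (they cannot be graded) though linkage does pull them in.
  `qa_count_override` supports the common practice of fixing a round
  sample size instead of an exact percentage.
* Selection operates at image level; patient-level referral semantics are
  a reporting concern, not part of the accuracy computation.
* Patient linkage defaults to the same screening round: a patient flagged
  in one year has their *other images from that visit* reviewed (one
  flagged patient-visit contributes exactly 2 eyes × 2 fields), which is
  the scope under which the canonical review-set accounting — positives
  plus linked images summing to 4 × flagged patient-visits — holds.
  `link_scope = "all"` extends linkage to every year of that patient.
* Image normalisation: centred crop retaining 90% of each *linear*
  dimension (it removes the circular camera mask symmetrically; 90% of
  area would crop less), then bilinear resize to 299×299, then
  subtraction of a Gaussian local average (σ = out_size/30 — the kernel
  for "local average colour" is a convention, recorded as such) with unit
  gain and re-centring on 50% gray. Crop precedes resize. A constant
  image maps exactly to the gray level, and a constant intensity offset
  is absorbed by the local average.

## Problem sizes

The test-suite simulations use 200–5,000-patient cohorts and 10^4–10^5
score draws — large enough that binomial/Monte-Carlo 3-SE bands are tight
(±0.009 on a grader operating point at n = 10^4; ±0.003 on an AUC at
n = 10^5) while the full suite stays fast enough to run habitually. The
acceptance script's end-to-end workflow uses a 2,000-patient, 8-year
cohort (~43,000 images).

## Known limitations

* Panel members grade independently given truth; real graders share
  training and correlate, which would lower consensus accuracy below the
  $1-(1-q)^k$ bound. A correlation term is future work.
* The two licensed ophthalmologists of a typical panel are not modelled
  as a distinct tier from the trained graders; the panel is one
  configurable list.
* Equal-variance binormal scores cannot express the fat-tailed score
  distributions some networks produce; the beta family is a partial
  remedy.
* The cost model is grading labour only — no referral costs, no QALYs,
  no discounting.
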
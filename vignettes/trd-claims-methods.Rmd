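---
title: "Methods: claims-based TRD phenotyping and burden estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based TRD phenotyping and burden estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdclaims)
```

## The problem

Treatment-resistant depression (TRD) — depression that fails to respond to
at least two adequate antidepressant trials — cannot be read off any single
field of an administrative claims record. It must be reconstructed from the
sequence of dated dispensings: which drug was started when, at what dose,
for how long, and what happened next. This package implements that
reconstruction as a deterministic, fully specified algorithm, together with
the downstream machinery (matching, outcome models) needed to estimate the
incremental healthcare utilization and cost associated with TRD, and a
synthetic claims generator that makes every step testable against known
ground truth.

## Cohort definition

The index date is a patient's first antidepressant dispensing inside the
configurable index window (default 2013-01-01 to 2014-09-30; a narrower
2013-01-01 to 2013-09-30 variant can be set via `study_params()` — both
readings of the enrollment window are defensible and neither is hard-coded).
Inclusion requires age 18–63 at index, a 183-day pre-index washout free of
depression treatment, a qualifying depression diagnosis within ±30 days of
index, a second antidepressant fill within 30 days of the end of the index
fill's supply, and continuous enrollment with both benefits over the
365-day baseline and 730-day follow-up. Month-denominated design windows
are implemented as fixed day counts (6 months = 183 days, 12 = 365,
24 = 730): day-exact arithmetic is reproducible where calendar-month
arithmetic is ambiguous, and every constant is overridable.

Two deliberate interpretations, both configurable:

* "Depression treatment" in the washout means any antidepressant or
  augmentation-class dispensing, ECT, TMS, or a psychotherapy procedure
  code — the source rule names the concept but not the code list.
* The refill-compliance rule (second fill, gap ≤ 30 days) is applied
  uniformly to all diagnosis categories rather than only to the
  non-major-depression categories; the alternative reading is narrower and
  would only relax the rule for a minority of patients.

Patients who die during follow-up are retained; their enrollment
requirement and person-time stop at death. Exclusions are psychosis,
schizophrenia, mania, bipolar disorder, or dementia codes at *any* time,
and lithium / thyroid hormone / antipsychotic / anticonvulsant mood
stabilizer dispensings or ECT/TMS during the washout.

## The TRD algorithm

Within the current treatment episode — operationalized as the maximal run
of antidepressant/augmentation supply from the index dispensing in which
uncovered gaps never exceed 180 days, a boundary chosen to be
self-consistent with the 180-day switch ceiling below — therapy lines are
built by classifying each new drug's first dispensing:

* **Day numbering.** The regimen start date is Day 1; a drug starting on
  Day k has a start-to-start gap of k − 1 days. Stated once, tested at
  every boundary.
* **Switch pathway** (no active supply at the new drug's start): the
  current drug is a failure iff the gap lies in [29, 180] days, both ends
  inclusive (inclusivity is not stated in words anywhere; both boundaries
  are named configuration constants and enumerated in tests).
* **Augmentation pathway** (new agent under active supply): Days 1–14 form
  a combination regimen; Day 15 or later closes the current line as an
  augmentation failure, and the new line carries the current drugs plus
  the added agent.
* **Non-qualifying switches** (gap ≤ 28 or > 180 within the episode)
  restart the current line on the new drug: the abandoned trial was not an
  adequate-duration failure, so it neither counts as a line nor records a
  failure. This keeps the invariant that only the final regimen has no
  failure mode.
* Augmentation-class agents starting with no regimen drug on supply cannot
  anchor an antidepressant regimen and are ignored for sequencing (they
  are recorded as orphans in the episode object).
* Same-drug refills and dose changes never start a new line; lines are
  keyed by canonical drug name.

A regimen is **dose-adequate** when at least one of its antidepressants
reaches the drug-specific minimum daily dose on a fill whose supply
overlaps the regimen (so titration that crosses the minimum mid-regimen
qualifies). The shipped minimum-dose table is an implementer-supplied
default in the spirit of practice-guideline minimums, not a transcription
of any published table, and should be reviewed per study. The patient is
labelled TRD when the episode reaches three regimens with the first two
dose-adequate and failure-terminated; the third regimen needs no adequacy
assessment — its initiation completes the definition.

The classifier is verified three ways: boundary enumeration over day
grids, equivalence with an independently coded brute-force rule evaluator
over one- and two-transition histories, and exact recovery of the
generator's scripted labels.

## Matching

The propensity model is a logistic regression of TRD status on age at
index, sex, diagnosis category, baseline anxiety / personality disorder /
substance abuse / PTSD flags, and the Elixhauser score (a count of
distinct comorbidity categories in the baseline year, 0–30 under the
shipped 30-category prefix map with combined hypertension; the map is a
simplified default meant to be replaced by a site-validated version for
real data).

Matching is sequential greedy nearest-neighbour without replacement at a
1:4 ratio and a caliper of 0.02. Two details the word "greedy" leaves
open are fixed and documented because the output depends on them: the
caliper is applied on the probability scale (no logit transformation is
implied by a width of 0.02) and is boundary-inclusive with a 1e-9
numerical tolerance; and cases are processed in descending propensity
order with patient-id tie-breaks (a seeded random order is available).
Variable-ratio matching (1 to 4 controls per case) is permitted — an
oversupplied pool yields exactly 4, a thin pool yields fewer, and a case
with no in-caliper control is dropped and reported. 1:1 matching for
sensitivity analyses is a parameter away.

## Outcome models

Utilization and costs are aggregated per patient-year: year 1 is
post-index days 1–365 (the index day is day 1), year 2 days 366–730,
assignment by service start date, inpatient length of stay summed over
stays starting in the year, and costs multiplied by a configurable
calendar-year inflation table (identity by default — the target price year
is a convention, not a computation this package should hide). Accounting
identities (payer total = medical + pharmacy, etc.) are enforced by
construction and tested exhaustively.

Adjusted comparisons, each controlling for the baseline value of the same
outcome:

* **Counts** (outpatient visits, hospital days): negative-binomial
  log-link GLM, with a Poisson fallback when the NB fit cannot converge
  (reported in the result's `family`).
* **Costs**: gamma log-link GLM; exact zeros are shifted by half the
  smallest positive cost (count reported) since the gamma family needs
  positive support; a normal-linear family is available as the sensitivity
  analysis, and a by-diagnosis-category subgroup analysis uses it with
  small subgroups skipped (fewer than 2 patients per arm) and the skip
  reason recorded.
* **Adjusted means** use recycled predictions: predict for the entire
  sample with TRD toggled on and off and average on the response scale.
  Whether the original analyses standardized this way is not knowable from
  the outside; recycled prediction is the interpretation implemented here
  because it reproduces "adjusted mean difference" semantics without
  per-group covariate drift.
* **Confidence intervals** are percentile bootstrap (2.5/97.5) over
  patient-level resamples drawn within arm, so both follow-up years of a
  patient move together and the case:control structure is respected. The
  conventional production setting is 1000 iterations; examples and tests
  use fewer. A resample on which the estimator fails is redrawn and
  counted; more than 10% failures aborts.
* **Binary outcomes** (any ED visit, any hospitalization) use a marginal
  logistic model over both years — TRD, year, TRD×year, baseline outcome,
  Elixhauser — fitted by hand-rolled generalized estimating equations with
  an exchangeable working correlation (independence available; the
  structure is a modelling choice, not something the estimand depends on)
  and a cluster-robust sandwich variance. Year-specific odds ratios come
  from the exposure and interaction terms with delta-method CIs.

Numerical choices in the GEE fitter: the quadratic forms are computed in
the standardized parameterization (Pearson residuals and
variance-weighted design), which keeps quasi-separated covariates — e.g. a
baseline indicator whose carriers happen to have no follow-up events at
small n — from inflating the working information matrix; iteration starts
from the intercept-only model, Fisher-scoring steps are damped to a
maximum coordinate of 2, the linear predictor is bounded at ±30, and a
relative 1e-10 ridge stabilizes the solves. A fit that stops at the
iteration cap is flagged `converged = FALSE` but still reports finite,
usable exposure contrasts.

## The synthetic claims generator

`generate_claims()` does not simulate disease progression; it *scripts*
pharmacy histories from parameterized templates so that each patient
satisfies or fails the TRD definition in a targeted, exactly known way:
three resistant templates (switch→switch, switch→augmentation,
augmentation→switch) and five non-resistant ones (single line, two lines,
switch gap too short, gap too long, inadequate first-line dose). Template
parameters (switch day, augmentation day, dose multiples, fill counts) are
drawn inside the qualifying ranges, including the exact boundaries, which
makes the classifier's acceptance surface deterministic: any
generator/classifier disagreement is a test failure, not noise.

Outcome structure mirrors the distributional assumptions of the analysis
models: annual total costs are gamma (generated per patient-year and
distributed over that year's claims proportionally to setting weights,
since the models only consume annual aggregates), outpatient visit counts
are negative-binomial, and ED/hospitalization indicators are Bernoulli
with year-specific odds-ratio effects. Defaults are chosen to look like a
commercially insured depression cohort: 13% resistant trajectories, mean
annual cost $8,800 in the comparison arm with gamma shape 1.5 (right-skewed,
coefficient of variation ≈ 0.8, typical of annual cost data), 8.5
outpatient visits per year decaying to 66% in year 2, 19% with an ED visit
and 5% hospitalized per year, cost ratio 1.40, visit ratio 1.35, ED odds
ratios 1.39/1.27 and hospitalization odds ratios 1.73/1.43 by year, 1% deaths
in follow-up. The cost and visit distribution parameters are free
parameters of the generator documented here, not empirical claims.
Resistance assignment is mildly covariate-dependent (anxiety, PTSD,
substance abuse, age, sex shift the log-odds around the target
prevalence), so the propensity and matching stages face genuine
confounding; the marginal prevalence stays within Monte-Carlo bounds of
the target.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real claims: coding noise and miscoded diagnoses,
plan-design heterogeneity, regional variation, partial-month supplies and
overlapping same-drug fills, medication discontinuation without
replacement, and any correlation between trajectory shape and cost beyond
the injected multiplicative effects. The pipeline's *correctness* on real
data follows from the rule implementations (tested on fixtures); its
*statistical behaviour* is established only under the generator's
assumptions.

## Verification sizes

Property checks run at sizes chosen to make their Monte-Carlo error small
relative to the tolerance being asserted: type-I error of the bootstrap
CIs over 200 null replicates of 250 patients per arm at 400 bootstrap
iterations; recovery of the injected cost ratio (1.40, within 10%), visit
ratio (1.35, within 10%) and odds ratios (within 15%) on a generated
bundle of 5,000 patients with balanced arms — a balanced split is the
standard design for estimator-recovery checks and is independent of the
13% study-condition prevalence, which is tested separately; matching
equivalence against a brute-force oracle on instances of up to 20
patients; and byte-identical end-to-end reports from repeated seeded runs
at 400 patients.

## Known limitations

* Dose adequacy uses fill-level daily dose against a single minimum; no
  averaging across overlapping same-drug fills.
* Psychotherapy-based treatment lines and cross-episode carry-over of
  failed trials are out of scope.
* The repeated-measures model treats the matched sample as independent
  clusters (patients); it does not model matched-set strata.
* The gamma zero-shift is a pragmatic device; two-part (hurdle) cost
  models are deliberately not implemented.
* The shipped Elixhauser map, dose table and code lists are documented
  defaults for synthetic data and algorithm testing, not validated
  clinical code sets.
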
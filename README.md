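# trdclaims

Claims-based phenotyping and economic burden analysis of
treatment-resistant depression (TRD).

Administrative pharmacy and medical claims are often the only large-scale
source for studying TRD, but everything of scientific interest — who is
treatment-resistant, what their care costs — has to be *derived* from dated
dispensings, diagnosis codes and enrollment spells. `trdclaims` implements
that derivation end to end for epidemiologists and health-economics
researchers:

* **Cohort construction** — incident antidepressant users 18–63 years old,
  with a 183-day treatment-free washout, a qualifying depression diagnosis
  (ICD-9 296.2x/296.3x except 296.25/296.30, 300.4, 309.0, 309.1, 311)
  within ±30 days of the index dispensing, a second antidepressant fill with
  a refill gap ≤ 30 days, and continuous enrollment over a 12-month baseline
  and 24-month follow-up (waived from death onward). Exclusions: psychotic,
  bipolar or dementia diagnoses at any time; lithium, thyroid hormone,
  antipsychotics, anticonvulsant mood stabilizers, ECT or TMS in the
  washout.
* **TRD phenotyping** — a line-of-therapy algorithm inside the current
  treatment episode (episodes end at a > 180-day supply gap). With the
  regimen start as Day 1, drug A fails by **switch** when a non-overlapping
  drug B starts 29–180 days after A (inclusive), and by **augmentation**
  when a second agent is added under active supply on Day 15 or later
  (Days 1–14 form a combination regimen instead). A patient is TRD when the
  episode reaches **3 regimens** and the first two were each dose-adequate
  (at or above a drug-specific guideline minimum) and ended in a qualifying
  failure.
* **Confounding control** — baseline covariates, a 30-category Elixhauser
  score, a logistic propensity model, and greedy 1:4 nearest-neighbour
  matching without replacement within a caliper of 0.02 on the probability
  scale.
* **Outcome models** — per patient-year utilization/cost aggregation;
  negative-binomial log-link GLMs for counts, gamma log-link GLMs for costs
  (linear-model sensitivity), adjusted for the baseline value of each
  outcome, with adjusted group means by recycled predictions and percentile
  bootstrap CIs; a repeated-measures logistic model (GEE, exchangeable
  working correlation, robust variance) for annual ED-visit and
  hospitalization indicators, giving year-specific odds ratios.
* **A synthetic claims generator** — scripted pharmacy trajectories with
  known ground truth (TRD prevalence, multiplicative cost and utilization
  effects), so every stage of the pipeline is testable without access to
  proprietary claims data.

## Worked example

```r
library(trdclaims)

cfg <- simulation_config(n_patients = 2000, seed = 42)  # 13% TRD trajectories
res <- run_trd_pipeline(cfg, iterations = 200, seed = 1)
print(res)
```

```
Treatment-resistant depression claims analysis
  cohort: 2000 eligible, 265 resistant (13.2%)
  matched: 263 cases : 1045 controls

Utilization:
             outcome year    estimate    ci_lower   ci_upper
   outpatient_visits    1  2.61597782  1.70067711 3.48303787
        hospital_los    1  0.08791189 -0.04861003 0.24070038
   outpatient_visits    2  2.23602900  1.53104096 3.01579500
        hospital_los    2 -0.05428257 -0.16090979 0.06795697
              any_ed    1  1.18569612  0.85497749 1.64434187
              any_ed    2  1.33012733  0.94925646 1.86381531
 any_hospitalization    1  1.64842594  0.92117343 2.94983334
 any_hospitalization    2  0.99071073  0.55158608 1.77942807

Costs:
                 outcome year estimate ci_lower ci_upper
        total_healthcare    1 2791.683 1665.094 3956.219
        total_healthcare    2 3469.298 2189.218 4757.007
 total_healthcare_linear    1 2793.135 1827.992 4190.628
```

Reading the output: the scripted 13% TRD prevalence is recovered by the
classifier (265/2000); after 1:4 caliper matching, TRD patients average
~2.6 more outpatient visits in follow-up year 1 (bootstrap 95% CI 1.70 to
3.48), the year-1 odds ratio for any ED visit is 1.19 and for any
hospitalization 1.65 (GEE), and adjusted total healthcare costs are
~$2,792 higher (95% CI $1,665 to $3,956) — consistent with the generator's
injected multiplicative effects (visit ratio 1.35, cost ratio 1.40, ED/
hospitalization odds ratios 1.39/1.73 in year 1). Matching halves the mean
absolute standardized difference of the propensity covariates (0.086 to
0.042 here; see `res$balance`).

Lower-level entry points mirror the pipeline stages:
`generate_claims()` / `write_bundle()` / `read_bundle()`,
`build_cohort()`, `build_treatment_episode()` / `classify_trd()` /
`classify_cohort()`, `fit_propensity()` / `greedy_match()` /
`balance_table()`, `annualize_outcomes()`, `fit_count_model()`,
`fit_cost_model()`, `fit_repeated_logistic()`,
`subgroup_costs_by_diagnosis()` and `render_reports()`.

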
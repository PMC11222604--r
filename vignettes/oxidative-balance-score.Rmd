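---
title: "The Oxidative Balance Score pipeline: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Oxidative Balance Score pipeline: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxbalance)
```

## The score

The Oxidative Balance Score (OBS) summarises a person's overall
antioxidant versus pro-oxidant exposure as an integer between 0 and
40. Twenty components each contribute 0, 1 or 2 points:

* **16 dietary components** — fiber, carotene, riboflavin, niacin,
  vitamins B6, B12, C and E, total folate, calcium, magnesium, zinc,
  copper and selenium (antioxidants), plus total fat and iron
  (pro-oxidants) — scored by position relative to *sex-specific
  tertile cutoffs*. Antioxidants earn 0/1/2 for the low/middle/high
  tertile; pro-oxidants the reverse.
* **4 lifestyle components** — physical activity (antioxidant:
  low/moderate/high activity earn 0/1/2), and three pro-oxidants:
  alcohol (heavy drinkers, at or above 30 g/d for men and 15 g/d for
  women, earn 0; lighter drinkers 1; non-drinkers 2), adiposity
  (obese 0, overweight 1, normal 2) and smoking (current 0, former 1,
  never 2).

Tertile intervals follow the transcription convention
`<= c1 / (c1, c2] / > c2`: a value exactly at a cutoff falls in the
lower group. `builtin_table1()` carries the fixed reference cutoffs;
`derive_cutoffs()` recomputes them as the sex-stratified empirical
1/3 and 2/3 quantiles of any cohort, using the inverse-ECDF quantile
definition (`type = 1`), under which the tertile cutoffs of the
values 1..9 are exactly (3, 6).

Two transcription gaps needed decisions. The reference scheme lists
no underweight BMI category; we score underweight (< 18.5 kg/m²) as
"normal" (2 points) since the pro-oxidant construct is adiposity —
configurable via `builtin_table1(underweight_score =)`. And the
scheme's female column for the middle smoking category is garbled in
the source; we read it as "former smoker", matching the male column.

Participants may be retained with up to three missing components
(the eligibility rule keeps anyone with at least 17 of 20 present).
By default a missing component contributes 0 points and completeness
is reported in `n_complete` (`missing_policy = "zero"`, the common
OBS convention); `missing_policy = "prorate"` instead rescales the
sum of observed scores to 20 components, which is no longer integer.

## Outcome and cohort pipeline

Serum uric acid (SUA) is analysed in µmol/L; hyperuricemia is
SUA ≥ 416 µmol/L (7 mg/dL) in men and ≥ 357 µmol/L (6 mg/dL) in
women, with the threshold itself a case (`mgdl_to_umol()` uses
59.48 µmol/L per mg/dL, rounded to the integer thresholds).

`apply_exclusions()` applies the complete-case chain in a fixed
order — age below 18, fewer than 17 complete OBS components, missing
SUA, missing covariates — counting each record at its **first**
failing stage, so stage counts always sum to `initial - final`.

Because OBS is right-skewed, the modelled exposure is `lnOBS =
log(OBS)` (undefined for a score of 0, which is flagged rather than
imputed). Quartiles are assigned by a rank-based rule suited to a
heavily tied integer score: the k-th boundary is the largest value
whose cumulative count does not exceed `k·n/4`, so ties fall to the
lower quartile and quartiles occupy contiguous integer ranges. The
rule uses only the ordering of the values, so quartiles of OBS and
of lnOBS agree element-wise; this tie-breaking choice is an inference
(the source never states one) justified by its reproducing the
published contiguous quartile ranges exactly.

## Association models

Three nested specifications are fitted for each outcome and exposure
parameterisation (continuous lnOBS, or quartile with Q1 reference):

* **Model 1** — unadjusted;
* **Model 2** — age, sex, race/ethnicity;
* **Model 3** — Model 2 plus BMI category, education, smoking,
  drinking, diabetes, hypertension and hyperlipidemia.

SUA uses least squares (β in µmol/L per unit lnOBS); hyperuricemia
uses maximum-likelihood logistic regression with exponentiated
coefficients (ORs). All intervals are large-sample Wald 95% CIs,
symmetric on the coefficient scale — the form the published
intervals take. Reference levels: female, Non-Hispanic White, lowest
education, "no" for binary conditions.

Fits are **unweighted by default**. Although the source describes a
weighted survey analysis, its printed unadjusted quartile ORs are
identical to the closed-form cross-product ORs of its unweighted
count table — which `crude_quartile_or()` reproduces with Woolf
intervals (`SE = sqrt(Σ 1/cell)`) — so unweighted fits are what the
printed numbers encode. A frequency-weight column is accepted via
`model_spec(weights =)`; design-based (Taylor-linearised) survey
variance is deliberately out of scope.

`subgroup_analysis()` refits the model inside each stratum (the
stratifier dropped from the covariates) and tests effect
modification with a Wald chi-square on the exposure-by-stratifier
product term(s) of the pooled model (likelihood-ratio by
`test = "lrt"`; the source does not name its test, and the two agree
closely at these sample sizes). Strata below `min_n`, or lacking
both outcome classes, are skipped with a warning and the pooled
interaction model is restricted to the fitted strata. Age subgroups
split at 60 years and BMI at 25/30 kg/m²; the source prints such
subgroups without stating cutpoints, so these defaults are flagged
as inferred.

## What the synthetic cohort emulates

`generate_cohort()` produces NHANES-like tables with a known
generative structure, so every stage is testable without microdata:

* **Intakes** are log-normal per component and sex — right-skewed
  and positive, the shape of dietary recall data — with
  `meanlog = (log c1 + log c2)/2` and
  `sdlog = (log c2 − log c1)/(2·Φ⁻¹(2/3))`, so each marginal's
  tertile boundaries sit exactly at the reference cutoffs and
  data-driven cutoffs concentrate near them.
* **A shared diet-quality factor** (`intake_cor`, default 0.55)
  equicorrelates the log-intakes without altering any marginal.
  Independent intakes would give an OBS standard deviation near 3.6
  — far narrower than real cohorts, where people who eat more of one
  nutrient eat more of most — partly because the two reversed
  dietary pro-oxidant scores cancel antioxidant spread. At 0.55 the
  simulated OBS is ≈ 20.4 ± 7.2, matching the ≈ 20.0 ± 7.2 observed
  in US adults.
* **SUA** is `baseline[sex] + obs_effect · lnOBS + N(0, sd)`, with
  lnOBS computed from the cohort's own data-driven cutoffs before
  missingness is applied, so the true conditional slope equals
  `obs_effect` exactly. Defaults: intercepts 400 (men) / 325 (women)
  µmol/L and noise SD 60, putting marginal SUA near 358/284 µmol/L
  and hyperuricemia prevalence near 14%; `obs_effect = −14` µmol/L
  per lnOBS unit, the magnitude of a fully adjusted US-adult
  estimate.
* **Lifestyle, covariates and missingness**: category probabilities
  near published US-adult marginals (BMI classes 1.5/26.6/32.3/39.6%,
  ever-smoking ≈ 44%, non-drinking ≈ 34%, hypertension 36%, diabetes
  14%, hyperlipidemia 35%, five-level race and education margins);
  physical activity has no published marginal and uses a
  0.35/0.35/0.30 split. Dietary values go missing completely at
  random, independently per component, at `missing_rate` (default
  0.02).

What it does **not** emulate: the survey's multistage sampling
design and weights, dietary measurement error and recall bias,
nutrient-specific correlation structure beyond the single shared
factor, non-Gaussian SUA tails, and confounding of the
exposure-outcome relation (the generative SUA depends on covariates
only through sex). Passing parameter-recovery tests therefore shows
the estimators are correct under a clean data-generating process,
not that real-data estimates are unbiased.

## Numerical and testing choices

Degenerate inputs fail loudly: identical tertile cutoffs, fewer than
three values per sex-stratum, fewer than four distinct quartile
values, zero contingency cells (no silent continuity correction),
constant exposures (singularity), and separated logistic fits all
raise informative errors. Missing values are signalled (`NA` scores,
empty CSV fields) and never collapsed to 0.

The test suite sizes its simulations to keep a full run around a
minute while leaving the stochastic checks comfortably powered:
slope recovery uses 100 replicates of n = 5000 (the generative slope
must fall inside its 95% CI in ≥ 90), interaction power uses 30
replicates of n = 6000 with sex-specific slopes −20/−8 (detection in
≥ 80%), and null calibration checks the interaction p-value against
uniformity over 60 replicates. Closed-form oracles back the
deterministic checks: hand-scored fixture records for the engine, an
order-statistic oracle for quantiles, and contingency-table ORs for
the unadjusted logistic fit (agreement to 1e-6 relative).

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(n_participants = 5000, seed = 1))
kept   <- apply_exclusions(cohort)$records
scored <- assign_quartiles(score_cohort(kept, derive_cutoffs(kept)))
fit_linear(scored, model_spec(1, "sua"))
fit_logistic(scored, model_spec(3, "hyperuricemia", "lnobs_quartile"))
```

The numbered scripts under `analysis/` run this pipeline at
n = 20,000 and write baseline tables, association tables and
subgroup forest data under `results/`.

## Known limitations

Adjusted (Model 2/3) coefficients from the real survey cannot be
reproduced without its microdata; the package validates their
machinery on synthetic cohorts instead. The synthetic generator's
covariates do not confound the exposure, so adjustment changes
estimates little by construction. Survey-design variance estimation
is out of scope, and the prorated missing-score policy, while
offered, makes lnOBS slightly incomparable across completeness
levels and is not the default.
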
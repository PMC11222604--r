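# oxbalance

Construction of the 20-component **Oxidative Balance Score (OBS)**
and analysis of its association with **serum uric acid (SUA)** and
**hyperuricemia**, as a tested, reusable R pipeline for
epidemiologists working with NHANES-style tabular cohorts.

The OBS summarises antioxidant versus pro-oxidant exposure: 16
dietary components (14 antioxidants, e.g. fiber, vitamins C/E,
selenium; 2 pro-oxidants, total fat and iron) scored 0–2 against
sex-specific intake tertiles, plus 4 lifestyle components (physical
activity as an antioxidant; alcohol, adiposity and smoking as
pro-oxidants) scored categorically. The total ranges 0–40; higher
means more antioxidant exposure. The modelled exposure is
lnOBS = log(OBS), both continuous and in cohort quartiles Q1–Q4:

* linear regression: SUA (µmol/L) = α + β·lnOBS + γ'X,
* logistic regression: logit P(hyperuricemia) = α + θ·lnOBS + γ'X,
  OR = e^θ, with hyperuricemia defined as SUA ≥ 416 µmol/L (men) /
  ≥ 357 µmol/L (women),

under nested covariate sets (Model 1 unadjusted; Model 2 age, sex,
race; Model 3 fully adjusted), with Wald 95% CIs, crude quartile
odds ratios OR = ad/bc with Woolf intervals, and subgroup analyses
with product-term interaction tests.

Because the underlying survey microdata are not bundled, the package
ships a synthetic cohort generator with a known generative effect
(`obs_effect` µmol/L of SUA per unit lnOBS) so that scoring,
exclusion, quartiling and model code are all verifiable end to end.

## Worked example

The numbered scripts under `analysis/` run the full pipeline on a
simulated cohort of 20,000 (including under-18s, so the exclusion
chain is exercised):

```sh
Rscript analysis/01_simulate.R        # raw cohort -> results/cohort_raw.csv
Rscript analysis/02_score_exclude.R   # score, exclude, quartile
Rscript analysis/03_associations.R    # Models 1-3, crude ORs
Rscript analysis/04_report.R          # baseline tables, subgroups
```

Stage 3 prints, for the default seed:

```
Model 1-3, lnOBS continuous vs SUA (umol/L per unit lnOBS):
 model estimate ci_low ci_high   p_value
     1   -12.66 -15.21  -10.10 2.778e-22
     2   -13.54 -15.71  -11.36 2.683e-34
     3   -13.45 -15.66  -11.24 9.413e-33

crude quartile ORs for hyperuricemia (Q1 reference):
 term         formatted       p
   Q1          1.0(ref)
   Q2 0.83 (0.74, 0.94)  0.0020
   Q3 0.70 (0.62, 0.79) <0.0001
   Q4 0.63 (0.56, 0.71) <0.0001
```

Every β estimate's 95% CI covers the generative effect of −14 µmol/L
per unit lnOBS, and the quartile odds ratios fall monotonically —
participants in the most antioxidant-balanced quartile have roughly
a third lower odds of hyperuricemia than Q1 in this simulation.

The same machinery is available programmatically:

```r
library(oxbalance)
cohort <- generate_cohort(cohort_config(n_participants = 5000, seed = 1))
kept   <- apply_exclusions(cohort)$records
scored <- assign_quartiles(score_cohort(kept, derive_cutoffs(kept)))
fit_linear(scored, model_spec(1, "sua"))
```

See `vignettes/oxidative-balance-score.Rmd` for the model,
assumptions, generator calibration and design decisions.

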
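# cvdstrat

Risk stratification for incident cardiovascular disease (CVD) by combining
**multiple polygenic risk scores** with **recalibrated pooled cohort
equations (PCE)**, evaluated with survival models — plus a calibrated
synthetic longitudinal cohort generator so the whole pipeline is testable
without access to any individual-level cohort data.

The package is aimed at statistical geneticists and cardiovascular
epidemiologists who want a reproducible, end-to-end implementation of the
multi-PRS + clinical-score stratification design: per-trait PRSs for
hypertension (HTN), myocardial infarction (MI), ischemic stroke (IS) and
coronary artery disease (CAD) are combined into a weighted sum, crossed with
the 7.5% ten-year clinical risk threshold, and the joint strata are tested
against incident events over a ~17-year biannual follow-up.

## The method

**Per-trait PRS.** For individual *i* and weight panel *w* over variants
*v*, the score is the additive dosage sum
`PRS_i = Σ_v d_iv · w_v`, with effect-allele resolution (dosages flipped to
`2 − d` when the coded allele is the panel's other allele). Scores are
normalized by the rank-based inverse-normal (Blom) transform. When no
external weight panel exists for a trait, weights are estimated by a
ten-fold **leave-one-group-out (LOGO)** cross-fit: samples are randomly
split into k groups, each group is scored with inverse-variance
meta-analyzed marginal GWAS effects estimated in the other k − 1 groups
only, so no sample's score ever uses its own group's phenotypes.

**wPRSsum.** The four normalized PRSs are combined through one multiple
logistic regression of prevalent CVD on the scores plus age and sex; the
per-trait coefficients β_t become combination weights:
`wPRSsum_i = Σ_t β_t · PRS_it`. Individuals are grouped into
low (bottom 20%) / intermediate (20–80%) / high (top 20%) genetic risk by
empirical quantiles.

**Recalibrated PCE.** Sex-specific linear sums on log-transformed risk
factors (age, total cholesterol, HDL, treated/untreated systolic blood
pressure, smoking, diabetes), converted to ten-year risk via
`risk = 1 − S0(10)^exp(sum − mean_sum)`, where the cohort mean sum and the
Kaplan–Meier baseline survival `S0(10)` are re-estimated on the target
cohort. Risk ≥ 7.5% defines the clinical high-risk group.

**Evaluation.** Cox proportional hazards models (Efron ties — the biannual
visit grid makes event times heavily tied), Kaplan–Meier curves, and
Harrell's concordance index for five nested models (age+sex; PRS; PRS+age+
sex; PCE; PCE+PRS), overall and within sex/age subgroups; plus the
six-stratum (PCE × genetic group) hazard-ratio table against the
double-low baseline.

**Synthetic cohorts.** `generate_study()` draws genotypes (binomial
dosages, no LD), per-trait causal architectures, sex-specific clinical
covariates, prevalent disease via a probit liability threshold, and
incident events from an exponential proportional-hazards model observed at
the first attended biannual visit, with per-visit dropout. The `"table1"`
preset is calibrated to a 7,612-person Korean population cohort profile
(51.7% female, age 52.1 ± 8.9, male/female smoking 48.8%/3.4%, 0.78%
prevalent and ~10% incident CVD, mean follow-up 13.3 years, median 16).

## Worked example

```r
library(cvdstrat)

cfg <- cvd_config(
  params = preset_params("table1", n_samples = 2000, n_variants = 300),
  logo_k = 5L, seed = 42)
report <- run_all(cfg)
print(report)
#> <cvd_report>
#>   input: 2000 samples, 300 variants
#>   qc: 0 variants and 4 samples removed
#>   prs: 4 traits scored (HTN via LOGO)
#>   exclusions: prevalent_cvd=10, missing_covariate=0, retained=1986
#>   analysis set: 1986 samples, 207 events

report$genetic_group_table
#> # A tibble: 4 × 6
#>   group                       n n_events hazard_ratio      se        p
#> 1 all (per SD of wPRSsum)  1986      207         1.21  0.0706  0.00788
#> 2 low                       399       33        NA    NA      NA
#> 3 intermediate             1196      121         1.23  0.196   0.289
#> 4 high                      391       53         1.75  0.222   0.0117

subset(report$model_cindex, subgroup == "all")
#>   model               subgroup     n n_events c_index
#> 1 age + sex           all       1986      207   0.558
#> 2 wprssum             all       1986      207   0.554
#> 3 wprssum + age + sex all       1986      207   0.574
#> 4 pce                 all       1986      207   0.570
#> 5 pce + wprssum       all       1986      207   0.576
```

Reading the output: the continuous weighted PRS carries a hazard ratio of
1.21 per SD for incident CVD; the top-20% genetic group has 1.75× the
hazard of the bottom 20%; and adding the PRS to either the demographic or
the clinical model nudges the concordance up (0.558 → 0.574 and
0.570 → 0.576 here). At this reduced sample size the confidence intervals
are wide — the generator's full-size preset gives tighter, more regular
gradients. `report$stratum_table` holds the six PCE × PRS strata,
`autoplot(report$km_genetic)` draws the Kaplan–Meier curves, and
`run_all(cfg, out_dir = "out")` writes every table as CSV beside a config
snapshot and run log.

Individual stages are ordinary data-frame functions and compose with the
pipe: `compute_prs()`, `normalize_scores()`, `logo_prs()`,
`fit_prs_weights()`, `combine_wprssum()`, `assign_genetic_groups()`,
`pce_linear_sum()`, `pce_recalibrate()`, `pce_risk()`,
`assign_pce_groups()`, `fit_cox()`, `km_curve()`, `c_index()`,
`evaluate_models()`; fitted objects have `tidy()`/`glance()` methods.

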
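---
title: "Methods: multi-PRS and pooled-cohort-equation risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-PRS and pooled-cohort-equation risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdstrat)
```

## Overview

`cvdstrat` implements a two-axis stratification of cardiovascular disease
(CVD) risk: a *genetic* axis built from several trait-specific polygenic
risk scores (PRSs) combined into a weighted sum (wPRSsum), and a
*clinical* axis given by sex-specific pooled cohort equations (PCE)
recalibrated to the analysis cohort. The axes are crossed into six strata
whose hazards for incident CVD are compared by Cox regression, and the
predictive value of each axis is summarized by Harrell's concordance
index. Because the motivating cohort design (a two-community Korean
population study followed biannually for 17 years) has no public
individual-level data, the package ships a synthetic-data generator whose
default preset reproduces that design's marginal structure; all tests and
examples run against it.

## The generative model

`generate_study()` simulates, in order:

1. **Genotypes.** Dosages are `Binomial(2, maf)` per variant with
   `maf ~ Uniform(maf_range)`, variants independent (no linkage
   disequilibrium). Variant metadata (empirical allele frequency, call
   rate, Hardy–Weinberg p, simulated imputation quality) is attached, and
   an optional corruption profile plants known violations of each QC
   filter for testing.
2. **Trait architectures.** For each of HTN, MI, IS and CAD,
   `n_causal_per_trait` variants get effects `N(0, trait_effect_sd²)`;
   the true per-trait score is the standardized dosage-weighted sum, and
   the causal effects are emitted as that trait's weight panel.
3. **Clinical covariates.** Sex first (`p_female`), then per-sex
   distributions: age as a truncated normal on [40, 69] whose underlying
   location is *solved* (by `uniroot` on the truncated-mean identity) so
   the truncated mean equals the configured target; cholesterol, HDL and
   SBP as positive normals; smoking, blood-pressure treatment and
   diabetes as Bernoulli draws.
4. **Prevalent disease.** A liability = standardized sum of the four true
   genetic scores + 0.5·z(age) + 0.25·1(male), passed through a probit
   with unit slope and an intercept solved so the expected prevalence
   equals `prevalence_target`. This gives the logistic weighting step a
   recoverable genetic signal at baseline.
5. **Incident events.** An exponential proportional-hazards model,
   `hazard_i = baseline_hazard · exp(lp_i)` with
   `lp = log_hr_genetic · z(genetic) + log_hr_clinical · z_sex(PCE sum)`,
   centered. The clinical predictor is standardized *within sex* so both
   sexes share an incidence scale, matching the near-equal male/female
   incidence of the emulated design.
6. **Observation.** Visits sit at `visit_interval · (1..K)` with
   `K = floor(max_followup / visit_interval)` (years 2–16 for the
   defaults). Everyone attends the first visit; after each attended visit
   a participant drops out with probability `dropout_prob_per_visit`. An
   event is recorded at the first *attended* visit at or after its raw
   time; otherwise the participant is censored at their last attended
   visit. All observed times are therefore grid multiples — which is also
   why the Cox fits default to Efron tie handling.

### The `"table1"` preset

The preset pins the covariate distributions to the emulated cohort's
published summary (n = 7,612; 51.72% female; male/female age
51.59 ± 8.72 / 52.49 ± 8.95; smoking 48.76% / 3.40%; SBP ≈ 117 mmHg;
TC ≈ 192 mg/dL; HDL ≈ 44–46 mg/dL; BP treatment 10.1% / 13.8%; diabetes
10.3% / 7.6%; prevalence 59/7,612). Two parameters are not directly
published and were calibrated once, by Monte Carlo on the generative
model itself, so that the *observed* follow-up distribution matches the
published mean 13.31 y / median 16 y and incidence 9.97%:
`dropout_prob_per_visit = 0.039` and `baseline_hazard = 0.0069 / y`, with
hazard effects `log_hr_genetic = 0.25` and `log_hr_clinical = 0.37` per
SD (a combined linear-predictor SD of ≈ 0.45 — a modest genetic gradient
and a roughly 1.5× stronger clinical gradient, in line with the relative
strength of PRS and clinical scores in this literature). These four
values are part of the preset's definition, not tuning knobs.

One published moment is unattainable by construction: the overall age SD
of 8.85 exceeds the SD of *any* normal truncated to [40, 69] (the uniform
limit caps it near 8.37), so the preset matches the age mean exactly and
accepts a slightly smaller SD. The real cohort's age distribution is
evidently not unimodal on this window.

### What the generator does **not** emulate

No linkage disequilibrium (so marginal GWAS effects are unbiased — a
deliberate simplification that makes the p-value-thresholded LOGO weights
well-defined without shrinkage), no genotyping batch structure, no
relatedness or ancestry structure, no competing risks, no time-varying
covariates, no recall bias in the self-reported outcome, and no
correlation between clinical covariates and genotypes beyond what the
prevalence liability induces. Passing tests therefore demonstrate the
*statistical machinery* is correct and leakage-free, not that real-data
effect sizes will match.

## Quality control

`filter_variants()` retains variants with call rate ≥ 0.95, HWE p ≥ 1e-6,
MAF ≥ 0.01 and imputation quality ≥ 0.8; `filter_samples()` retains
samples with call rate ≥ 0.97 and heterozygosity within ±3 SD of the
cohort mean. Exclusions are strict `<` comparisons, so values exactly at
a threshold survive. The HWE test is the asymptotic 1-df chi-square
against expected proportions at the empirical allele frequency (the
standard choice at these sample sizes; an exact test would matter only
for very rare variants, which the MAF filter removes anyway), returning
p = 1 for monomorphic variants where no departure is testable. The ±3 SD
heterozygosity band quantifies "excessive heterozygosity", for which no
published number exists. Filters run one pass, variants then samples;
sex-discrepancy, relatedness and ancestry-outlier checks are out of scope
and the QC report says so. Missing dosages are `NA`; call rates derive
from them, and scoring/GWAS mean-impute them per variant.

## PRS engine

* `compute_prs()` is the additive dosage-weight sum with effect-allele
  resolution: the panel's effect allele is counted directly, flipped
  (`2 − d`) when it matches the genotype panel's other allele, and the
  variant is skipped (with a warning count) when neither allele matches.
* `normalize_scores()` defaults to the rank-based inverse-normal
  transform with Blom offset, `Φ⁻¹((r − 3/8)/(n + 1/4))` — "normalized to
  a normal distribution" is read as a normalizing transform, not mere
  standardization; plain z-scoring is available by argument.
* `run_gwas()` fits, per variant, the univariate logistic regression of
  phenotype on dosage by IRLS vectorized across variants (tolerance 1e-8,
  ≤ 30 iterations). Separated fits are clamped at |β| = 10, flagged, and
  their p-value replaced by the Rao score test at β = 0, which remains
  finite under separation. Agreement with `glm()` is enforced in tests at
  1e-6.
* `meta_analyze()` is fixed-effect inverse-variance; infinite standard
  errors get zero weight.
* `logo_prs()` partitions samples into k groups (seeded uniform draw,
  unstratified; redrawn up to a retry limit if a group lacks a phenotype
  class), runs one GWAS per group, and scores each group with the
  meta-analysis of the *other* k − 1 groups converted to weights by a
  p-value threshold rule (default threshold 1: all variants). Running
  one GWAS per group and meta-analyzing complements is algebraically the
  same as re-running the GWAS per held-out group, at a k-fold saving.
  The weight rule is a pluggable function so externally produced
  (e.g. shrinkage-based) weights can be slotted in; LD-aware shrinkage
  itself needs an LD reference and is out of scope — with LD-free
  synthetic variants, marginal meta-betas are unbiased weights.

The no-leakage property — a group's scores are unchanged under any
permutation of that group's own phenotype labels — is tested directly.

## wPRSsum and genetic groups

`fit_prs_weights()` fits one multiple logistic regression of prevalent
disease on all included normalized PRSs plus age and sex;
`combine_wprssum()` applies only the per-trait coefficients (intercept
and covariate terms excluded — covariates re-enter through Cox adjustment
and through the PCE axis). The weighting step deliberately uses prevalent
cases, which are subsequently *excluded* from the incidence analysis;
`run_all()` enforces that ordering.

`assign_genetic_groups()` cuts at the 20th and 80th percentiles
(type-7 quantiles) with half-open intervals `[min, q20) / [q20, q80) /
[q80, max]` — a score exactly at a cutpoint falls upward. The cutpoint
base set defaults to *all genotyped samples before exclusions* (the
emulated design's published group sizes are not exact quintiles of its
post-exclusion count, which this convention reproduces); it is
configurable to post-exclusion.

`prs_association_scan()` reports, for each of the 2⁴ − 1 trait subsets,
the age/sex-adjusted odds ratio of prevalent disease per SD of that
subset's combined score. Per-SD scaling is a documented reporting choice
that makes rows of different subset sizes comparable.

## PCE scoring and recalibration

The shipped coefficient preset is the recalibrated East-Asian set, kept
to the printed three decimals. The treated/untreated blood-pressure
convention sets `TRSBP = SBP, UNSBP = 1` when treated and the reverse
otherwise, so exactly one pathway is active per person and the inactive
log terms vanish — the only encoding that keeps the published template
coherent. The men's equation carries an age×smoking interaction; the
women's carries age×log-SBP interactions on both pathways.

`pce_recalibrate()` estimates, per sex, the cohort mean linear sum and
the 10-year Kaplan–Meier baseline survival; these are *never* hard-coded
(the source publication does not print them). In `run_all()` the
recalibration uses the post-exclusion incident-analysis set, since
prevalent cases carry no interpretable incident follow-up. Risk is
`1 − S0(10)^exp(sum − mean_sum)`, and the 7.5% threshold is inclusive on
the high side. The 10-year horizon is fixed even though follow-up runs
longer, matching the convention the equations were built for.

## Survival evaluation

`fit_cox()` wraps `survival::coxph` with Efron ties (accurate under the
heavy grid ties); constant covariates are dropped with a warning and a
monotone likelihood is an error. `km_curve()` is the product-limit
estimator with censorings at a tied time kept in that time's risk set.
`c_index()` is Harrell's estimator via `survival::concordance`
(reverse orientation: a pair is comparable when the earlier time is an
event, or the times tie with the later one censored; score ties count ½)
— tests verify exact agreement with an O(n²) pair enumeration.

`evaluate_models()` fits the five standard models and reports the
concordance of each Cox fit's linear predictor (for a single covariate
this equals the covariate's own concordance; for multivariable models
the refitted predictor is the documented choice). The PCE enters models
4–5 as the calibrated 10-year *risk*, not the raw linear sum: the two
sexes' sums sit on entirely different numeric scales (the women's printed
coefficients are ~30× the men's), so a pooled model on raw sums cannot
rank across sexes, while the per-sex risk transform puts everyone on one
probability scale — which is also why model 5 needs no age/sex terms.
Degenerate subgroup fits yield missing cells rather than errors.

`stratum_cox()` fits one age/sex-adjusted model with the six-stratum
factor (baseline: clinical-low/genetic-low) and reports per-stratum
indicator hazard ratios with Wald SE and p, the table layout the design
calls for; empty strata stay as rows with missing estimates.

## Numerical and testing choices

Problem sizes in the test suite are chosen to keep the full suite around
half a minute: oracle comparisons run at n ≤ 20 (exhaustive enumeration),
parameter-recovery checks at n = 5,000–20,000 for closed-form models, and
replicate experiments for the stratum-ordering and concordance-dominance
properties at 50 replicates of n = 2,500 with 150 variants. In those
replicates the prevalent-case *count* (~59) rather than the prevalence
*rate* is held at the full design's value, because the stability of the
logistic weighting step depends on the number of cases, not the rate;
with the full-size rate at n = 2,500 the weighting model would be fit on
~19 cases and its noise would dominate what is meant to be a test of the
hazard structure. The acceptance script, by contrast, always runs the
full n = 7,612 preset unmodified.

Other conventions: IRLS and Cox tolerances are 1e-8; the brute-force
partial-likelihood oracle must agree to 1e-6; quantiles are type 7;
factor baselines are the first level; all randomness flows from explicit
seeds and identical seed + parameters give bit-identical outputs,
including written files.

## Known limitations

Single-ancestry, LD-free genetics; a constant baseline hazard (Weibull
shape would be the natural config extension); no competing risks; the
LOGO stand-in uses marginal rather than shrinkage weights, so on real,
LD-structured data externally produced weight panels should be supplied;
and the PCE recalibration inherits the usual caveat that recalibrating
and evaluating on the same cohort flatters the clinical score.
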
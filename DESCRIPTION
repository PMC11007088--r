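Package: cvdstrat
Title: Cardiovascular Risk Stratification with Multi-Polygenic Scores and
    Pooled Cohort Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying cardiovascular disease (CVD) risk by
    combining several trait-specific polygenic risk scores (PRS) into a
    logistic-weighted sum (wPRSsum) and pairing it with recalibrated pooled
    cohort equations (PCE). Includes a synthetic longitudinal cohort
    generator with genotypes, clinical covariates, baseline (prevalent)
    disease and interval-detected incident events on a biannual visit grid;
    genotype quality control (call rate, Hardy-Weinberg equilibrium, minor
    allele frequency, imputation quality); per-trait PRS computation with a
    leave-one-group-out cross-fitting scheme that prevents weight leakage;
    sex-specific PCE linear sums with cohort recalibration of the mean sum
    and 10-year baseline survival; and survival-based evaluation via Cox
    proportional hazards models, Kaplan-Meier curves and Harrell's
    concordance index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
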
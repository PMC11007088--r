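# truncated-normal helpers: sampling by inverse CDF; the underlying
# location is solved so the *truncated* mean equals the requested target
rtruncnorm <- function(n, mu, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  qnorm(p, mu, sd)
}

truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

solve_truncnorm_mu <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi)
    abort("solve_truncnorm_mu: target mean must lie inside the bounds")
  uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
          interval = c(lo - 3 * sd, hi + 3 * sd), tol = 1e-10)$root
}

#' Simulate clinical covariates for a cohort
#'
#' Draws sex, age and the clinical risk factors of a pooled-cohort-style
#' record per participant, with sex-specific distributions. Age is a
#' truncated normal on the cohort age window whose underlying location is
#' solved so the truncated mean hits the configured per-sex mean exactly;
#' cholesterol, HDL and SBP are normal (resampled into the positive
#' range); smoking, blood-pressure treatment and diabetes are Bernoulli
#' with per-sex prevalences.
#'
#' @param params a [sim_params()] object.
#' @return A tibble with columns `sample_id`, `sex` (`"male"`/`"female"`),
#'   `age`, `tc`, `hdl`, `sbp`, `bp_treated`, `smoker`, `diabetes`.
#' @export
simulate_covariates <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  cp <- params$covariate_params
  n <- params$n_samples
  lo <- cp$age_range[1]
  hi <- cp$age_range[2]
  sex <- ifelse(runif(n) < cp$p_female, "female", "male")

  draw_pos <- function(n, mean, sd) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  out <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n)), sex = sex,
    age = NA_real_, tc = NA_real_, hdl = NA_real_, sbp = NA_real_,
    bp_treated = NA_integer_, smoker = NA_integer_, diabetes = NA_integer_)
  for (s in c("male", "female")) {
    p <- cp[[s]]
    i <- which(sex == s)
    if (!length(i)) next
    mu <- solve_truncnorm_mu(p$age_mean, p$age_sd, lo, hi)
    out$age[i] <- rtruncnorm(length(i), mu, p$age_sd, lo, hi)
    out$tc[i] <- draw_pos(length(i), p$tc_mean, p$tc_sd)
    out$hdl[i] <- draw_pos(length(i), p$hdl_mean, p$hdl_sd)
    out$sbp[i] <- draw_pos(length(i), p$sbp_mean, p$sbp_sd)
    out$smoker[i] <- rbinom(length(i), 1L, p$p_smoker)
    out$bp_treated[i] <- rbinom(length(i), 1L, p$p_bp_treated)
    out$diabetes[i] <- rbinom(length(i), 1L, p$p_diabetes)
  }
  out
}

#' Assign prevalent (baseline) disease by liability threshold
#'
#' Standardizes the supplied liability and flags each sample prevalent
#' with probability `pnorm(alpha + z)` (probit link, unit slope), where
#' the intercept `alpha` is solved so the expected prevalence equals
#' `target`. Higher liability therefore always means a higher chance of
#' being prevalent, and the expected case count is `n * target`.
#'
#' @param liability numeric vector of finite liabilities.
#' @param target target prevalence in \[0, 1); 0 gives no cases.
#' @param seed optional integer seed for just this draw.
#' @return Integer vector of 0/1 prevalent flags.
#' @export
assign_prevalent <- function(liability, target, seed = NULL) {
  if (any(!is.finite(liability)))
    abort("assign_prevalent: liability must be finite")
  if (length(target) != 1 || target < 0 || target >= 1)
    abort("assign_prevalent: target must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(liability)
  if (target == 0) return(integer(n))
  z <- if (sd(liability) > 0) as.numeric(scale(liability)) else rep(0, n)
  alpha <- uniroot(function(a) mean(pnorm(a + z)) - target,
                   interval = c(-40, 40), tol = 1e-12)$root
  rbinom(n, 1L, pnorm(alpha + z))
}

#' Simulate interval-detected survival outcomes on a visit grid
#'
#' Events follow an exponential proportional-hazards model,
#' `hazard_i = baseline_hazard * exp(lp_i)`. Follow-up visits sit at
#' `visit_interval * (1, 2, ..., K)` with `K = floor(max_followup /
#' visit_interval)`; every participant attends the first visit and drops
#' out after each attended visit with probability
#' `dropout_prob_per_visit`. An event is recorded at the first *attended*
#' visit at or after its raw occurrence time; otherwise the participant
#' is censored at their last attended visit. All observed times are
#' therefore multiples of `visit_interval`.
#'
#' @param linear_predictor per-sample log-hazard offsets; callers should
#'   center them (mean ~ 0) so `baseline_hazard` keeps its meaning.
#' @param params a [sim_params()] object.
#' @return A tibble with columns `time_years` and `event` (0/1).
#' @export
simulate_survival <- function(linear_predictor, params) {
  stopifnot(inherits(params, "sim_params"))
  bad <- which(!is.finite(linear_predictor))
  if (length(bad))
    abort(paste0("simulate_survival: non-finite linear predictor for sample(s) ",
                 toString(head(bad, 5))))
  n <- length(linear_predictor)
  dt <- params$visit_interval
  K <- floor(params$max_followup / dt)
  n_attended <- pmin(rgeom(n, max(params$dropout_prob_per_visit, 1e-12)) + 1L, K)
  if (params$dropout_prob_per_visit == 0) n_attended <- rep(K, n)
  censor_time <- dt * n_attended
  rate <- params$baseline_hazard * exp(linear_predictor)
  raw <- ifelse(rate > 0, rexp(n, pmax(rate, 1e-300)), Inf)
  detect_visit <- ceiling(raw / dt)          # first grid visit at/after event
  detected <- detect_visit <= n_attended
  tibble::tibble(
    time_years = ifelse(detected, dt * detect_visit, censor_time),
    event = as.integer(detected))
}

#' Generate a complete synthetic study
#'
#' End-to-end fixture generator: genotypes, per-trait causal
#' architectures and weight panels, clinical covariates, prevalent
#' disease via a liability threshold, and incident events under a
#' proportional-hazards model observed on the visit grid. The ground
#' truth (causal variants, effects, true scores, generative hazards) is
#' returned so parameter-recovery tests can compare estimates with truth.
#'
#' The prevalent-disease liability is the standardized sum of the four
#' true per-trait genetic scores plus age and male-sex terms; the
#' incident-event log hazard is `log_hr_genetic` times the standardized
#' combined genetic score plus `log_hr_clinical` times the within-sex
#' standardized clinical (PCE-sum) linear predictor.
#'
#' @param params a [sim_params()] object, e.g. from [preset_params()].
#' @return A list of class `cvd_study`: `genotypes`
#'   ([genotype_matrix()]), `weights` (named list of per-trait weight
#'   panels), `cohort` (tibble, one row per participant), `truth`
#'   (generative ground truth), `params`.
#' @export
generate_study <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  geno <- sample_genotypes(params)
  cov <- simulate_covariates(params)

  dos <- geno$dosages
  dos_c <- dos
  if (anyNA(dos_c)) {            # mean-impute for score construction only
    af2 <- colMeans(dos_c, na.rm = TRUE)
    idx <- which(is.na(dos_c), arr.ind = TRUE)
    dos_c[idx] <- af2[idx[, 2]]
  }
  weights <- list()
  true_scores <- matrix(0, nrow(dos), length(params$traits),
                        dimnames = list(rownames(dos), params$traits))
  causal <- list()
  for (tr in params$traits) {
    idx <- sample.int(ncol(dos), params$n_causal_per_trait)
    beta <- rnorm(params$n_causal_per_trait, 0, params$trait_effect_sd)
    raw <- as.numeric(dos_c[, idx, drop = FALSE] %*% beta)
    true_scores[, tr] <- if (sd(raw) > 0) as.numeric(scale(raw)) else raw
    weights[[tr]] <- tibble::tibble(
      variant_id = geno$variants$variant_id[idx],
      effect_allele = geno$variants$effect_allele[idx],
      weight = beta)
    causal[[tr]] <- idx
  }
  genetic <- rowSums(true_scores)
  genetic <- if (sd(genetic) > 0) as.numeric(scale(genetic)) else genetic

  # clinical predictor: the PCE linear sum standardized within sex, so the
  # two sexes share an incidence scale (as observed in the target cohort)
  clin_raw <- pce_linear_sum(cov)$pce_sum
  clinical <- ave(clin_raw, cov$sex, FUN = function(x)
    if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)

  liab <- genetic + 0.5 * as.numeric(scale(cov$age)) +
    0.25 * (cov$sex == "male")
  prevalent <- assign_prevalent(liab, params$prevalence_target)

  lp <- params$log_hr_genetic * genetic + params$log_hr_clinical * clinical
  lp <- lp - mean(lp)
  surv <- simulate_survival(lp, params)

  cohort <- dplyr::bind_cols(cov,
                             tibble::tibble(prevalent_cvd = prevalent),
                             surv)
  structure(list(
    genotypes = geno, weights = weights, cohort = cohort,
    truth = list(causal = causal, true_scores = true_scores,
                 genetic = genetic, clinical = clinical,
                 linear_predictor = lp,
                 log_hr_genetic = params$log_hr_genetic,
                 log_hr_clinical = params$log_hr_clinical),
    params = params), class = "cvd_study")
}

#' @export
print.cvd_study <- function(x, ...) {
  cat(sprintf(paste0("<cvd_study> %d samples, %d variants, traits: %s\n",
                     "  prevalent %d, incident %d, mean follow-up %.2f y\n"),
              nrow(x$cohort), ncol(x$genotypes$dosages),
              toString(x$params$traits), sum(x$cohort$prevalent_cvd),
              sum(x$cohort$event), mean(x$cohort$time_years)))
  invisible(x)
}

#' Write a generated study to disk
#'
#' Emits the dosage + variant TSVs, one weight panel TSV per trait, the
#' cohort CSV and (optionally) a dosage VCF into `dir`.
#'
#' @param study a `cvd_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @param vcf also write `genotypes.vcf`?
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir, vcf = FALSE) {
  stopifnot(inherits(study, "cvd_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_tsv(study$genotypes, file.path(dir, "dosages.tsv"),
                   file.path(dir, "variants.tsv"))
  for (tr in names(study$weights))
    write_weight_panel(study$weights[[tr]],
                       file.path(dir, paste0("weights_", tr, ".tsv")))
  readr::write_csv(study$cohort, file.path(dir, "cohort.csv"))
  if (vcf) write_vcf_dosage(study$genotypes, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}

#' Read a cohort table written by [write_study()]
#' @param path path to `cohort.csv`.
#' @return The cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", sex = "c",
                                          .default = readr::col_guess()))
}
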
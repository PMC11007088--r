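test_that("genotype sampling respects allele frequencies and HWE structure", {
  set.seed(11)
  p <- sim_params(n_samples = 4000, n_variants = 3, maf_range = c(0.5, 0.5))
  g <- sample_genotypes(p)
  expect_equal(unname(colMeans(g$dosages)), rep(1, 3), tolerance = 0.05)
  counts <- table(g$dosages[, 1])
  expect_equal(as.numeric(counts / sum(counts)), c(0.25, 0.5, 0.25),
               tolerance = 0.06)
  expect_true(all(g$variants$hwe_p > 1e-6))
})

test_that("genotype sampling is deterministic and validates maf_range", {
  p <- sim_params(n_samples = 10, n_variants = 5, seed = 3)
  set.seed(3)
  g1 <- sample_genotypes(p)
  set.seed(3)
  g2 <- sample_genotypes(p)
  expect_identical(g1$dosages, g2$dosages)
  expect_error(sim_params(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_params(maf_range = c(0.3, 0.1)), "maf_range")
})

test_that("covariates track the configured per-sex distributions", {
  set.seed(5)
  p <- preset_params("table1")
  cov <- simulate_covariates(p)
  expect_equal(nrow(cov), 7612)
  # truncated-normal location is solved, so the mean matches the target
  expect_lt(abs(mean(cov$age) - 52.06), 3 * 8.85 / sqrt(7612))
  expect_true(all(cov$age >= 40 & cov$age <= 69))
  m <- cov$sex == "male"
  se_m <- sqrt(0.4876 * (1 - 0.4876) / sum(m))
  expect_lt(abs(mean(cov$smoker[m]) - 0.4876), 3 * se_m)
  se_f <- sqrt(0.034 * (1 - 0.034) / sum(!m))
  expect_lt(abs(mean(cov$smoker[!m]) - 0.034), 3 * se_f)
  expect_true(all(cov$tc > 0 & cov$hdl > 0 & cov$sbp > 0))
})

test_that("zero smoking prevalence yields zero smokers", {
  set.seed(6)
  cp <- covariate_params()
  cp$male$p_smoker <- 0
  cp$female$p_smoker <- 0
  cov <- simulate_covariates(sim_params(n_samples = 500,
                                        covariate_params = cp))
  expect_identical(sum(cov$smoker), 0L)
})

test_that("prevalent assignment hits its target and respects liability order", {
  set.seed(8)
  liab <- rnorm(7612)
  expect_identical(assign_prevalent(liab, 0), integer(7612))
  flags <- assign_prevalent(liab, 59 / 7612, seed = 1)
  se <- sqrt((59 / 7612) * (1 - 59 / 7612) / 7612)
  expect_lt(abs(mean(flags) - 59 / 7612), 3 * se)
  # strongly separated liabilities: high-liability sample flagged more often
  hits <- vapply(1:500, function(s) {
    f <- assign_prevalent(c(-3, 3), 0.5, seed = s)
    f[2] - f[1]
  }, integer(1))
  expect_gt(mean(hits), 0.3)
  expect_error(assign_prevalent(c(1, NA), 0.5), "finite")
  expect_error(assign_prevalent(rnorm(5), 1.2), "target")
})

test_that("survival times live on the visit grid with interval detection", {
  p <- sim_params(n_samples = 300, baseline_hazard = 0,
                  dropout_prob_per_visit = 0.1)
  set.seed(2)
  s0 <- simulate_survival(rep(0, 300), p)
  expect_true(all(s0$event == 0))
  expect_true(all(s0$time_years %% 2 == 0))

  p2 <- sim_params(n_samples = 400, baseline_hazard = 0.02,
                   dropout_prob_per_visit = 0, max_followup = 17)
  set.seed(3)
  s2 <- simulate_survival(rep(0, 400), p2)
  expect_true(all(s2$time_years[s2$event == 0] == 16))
  expect_true(all(s2$time_years %% 2 == 0))
  expect_true(all(s2$time_years <= 17 + 2))
  expect_error(simulate_survival(c(0, Inf), p2), "sample")
})

test_that("Cox recovery: two-group hazard ratio 2 is recovered on the grid", {
  set.seed(9)
  n <- 20000
  grp <- rep(0:1, each = n / 2)
  p <- sim_params(n_samples = n, baseline_hazard = 0.05,
                  dropout_prob_per_visit = 0)
  s <- simulate_survival(log(2) * (grp - 0.5), p)
  fit <- fit_cox(dplyr::mutate(s, grp = grp), "grp")
  td <- tidy(fit)
  expect_lt(abs(td$estimate - log(2)), 3 * td$std.error)
})

test_that("raising the genetic hazard effect raises incident counts", {
  events_at <- function(loghr, reps) {
    vapply(seq_len(reps), function(r) {
      st <- small_study(n = 500, m = 30, seed = 1000 + r,
                        log_hr_genetic = loghr)
      sum(st$cohort$event)
    }, numeric(1))
  }
  lo <- events_at(0, 50)
  hi <- events_at(0.8, 50)
  expect_gt(mean(hi), mean(lo))
  expect_lt(stats::t.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("generate_study is deterministic down to the written bytes", {
  st1 <- small_study(n = 80, m = 12, seed = 42)
  st2 <- small_study(n = 80, m = 12, seed = 42)
  expect_identical(st1$cohort, st2$cohort)
  expect_identical(st1$genotypes$dosages, st2$genotypes$dosages)
  expect_identical(st1$weights, st2$weights)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(st1, d1, vcf = TRUE)
  write_study(st2, d2, vcf = TRUE)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("study files round-trip through their plain-text formats", {
  st <- small_study(n = 40, m = 8, seed = 21)
  d <- withr::local_tempdir()
  write_study(st, d, vcf = TRUE)
  g <- read_dosage_tsv(file.path(d, "dosages.tsv"),
                       file.path(d, "variants.tsv"))
  expect_equal(g$dosages, st$genotypes$dosages)
  expect_equal(g$variants$variant_id, st$genotypes$variants$variant_id)
  w <- read_weight_panel(file.path(d, "weights_HTN.tsv"))
  expect_equal(w$weight, st$weights$HTN$weight)
  co <- read_cohort_csv(file.path(d, "cohort.csv"))
  expect_equal(co$time_years, st$cohort$time_years)
  # VCF dosages agree with the matrix when read back by an independent parser
  skip_if_not_installed("vcfR")
  v <- suppressMessages(vcfR::read.vcfR(file.path(d, "genotypes.vcf"),
                                        verbose = FALSE))
  ds <- vcfR::extract.gt(v, "DS", as.numeric = TRUE)
  expect_equal(unname(t(ds)), unname(st$genotypes$dosages))
})

test_that("null preset produces flat risk gradients downstream", {
  st <- small_study(n = 2500, m = 40, seed = 77, preset = "null")
  co <- st$cohort
  grp <- as.integer(cut(st$truth$genetic, quantile(st$truth$genetic,
                                                   c(0, .2, .8, 1)),
                        include.lowest = TRUE))
  fit <- fit_cox(dplyr::mutate(co, g = factor(grp)), "g")
  expect_true(all(abs(tidy(fit)$estimate) < 3 * tidy(fit)$std.error))
})
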
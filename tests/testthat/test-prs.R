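test_that("compute_prs reduces correctly on degenerate panels", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 3)
  g <- make_geno(d)
  zero <- tibble::tibble(variant_id = c("v001", "v002"),
                         effect_allele = "A", weight = c(0, 0))
  expect_equal(compute_prs(g, zero)$score, c(0, 0, 0))
  one <- tibble::tibble(variant_id = "v001", effect_allele = "A",
                        weight = 0.5)
  expect_equal(compute_prs(g, one)$score, c(0, 0.5, 1))
})

test_that("compute_prs equals the double-loop oracle, including flips", {
  set.seed(41)
  d <- matrix(sample(0:2, 20, replace = TRUE), nrow = 5)
  g <- make_geno(d)
  g$variants$effect_allele <- c("A", "G", "A", "G")
  g$variants$other_allele <- c("G", "A", "G", "A")
  panel <- tibble::tibble(
    variant_id = c("v001", "v002", "v003", "v004"),
    effect_allele = c("A", "A", "A", "G"),   # v002 needs flipping
    weight = rnorm(4))
  got <- compute_prs(g, panel)
  expect_equal(got$score, oracle_prs(d, g$variants, panel))
  expect_equal(attr(got, "n_flipped"), 1L)
})

test_that("compute_prs handles mismatches, absences and missing dosages", {
  d <- matrix(c(0, 1, 2, NA, 1, 0), nrow = 3)
  g <- make_geno(d)
  panel <- tibble::tibble(
    variant_id = c("v001", "v002", "ghost"),
    effect_allele = c("A", "T", "A"),        # v002 matches neither allele
    weight = c(1, 1, 1))
  expect_warning(got <- compute_prs(g, panel), "mismatch")
  expect_equal(attr(got, "n_mismatched"), 1L)
  expect_equal(attr(got, "n_missing"), 1L)
  expect_equal(got$score, d[, 1], ignore_attr = TRUE)
  bad <- tibble::tibble(variant_id = "nope", effect_allele = "A", weight = 1)
  expect_error(compute_prs(g, bad), "overlap")
  # missing dosage mean-imputed as the column mean
  p2 <- tibble::tibble(variant_id = "v002", effect_allele = "A", weight = 2)
  expect_equal(compute_prs(g, p2)$score, 2 * c(0.5, 1, 0))
})

test_that("compute_prs is linear in the weight panel", {
  set.seed(42)
  d <- matrix(sample(0:2, 60, replace = TRUE), nrow = 6)
  g <- make_geno(d)
  mk <- function(w) tibble::tibble(variant_id = colnames(g$dosages),
                                   effect_allele = "A", weight = w)
  wa <- rnorm(10)
  wb <- rnorm(10)
  expect_equal(compute_prs(g, mk(wa + wb))$score,
               compute_prs(g, mk(wa))$score + compute_prs(g, mk(wb))$score)
})

test_that("inverse-normal transform follows the Blom formula and keeps ranks", {
  x <- c(2.3, -1.1, 0.4, 9.9, 0.0)
  expect_equal(normalize_scores(x),
               qnorm((rank(x) - 3 / 8) / (5 + 1 / 4)))
  z <- qnorm((1:100 - 3 / 8) / 100.25)
  expect_equal(normalize_scores(z), z)   # already Blom quantiles
  set.seed(43)
  y <- rexp(200)
  expect_equal(cor(y, normalize_scores(y), method = "spearman"), 1)
  expect_error(normalize_scores(rep(1, 5)), "constant")
  expect_equal(normalize_scores(x, method = "zscore"), as.numeric(scale(x)))
})

test_that("large-sample inverse-normal output passes a normality test", {
  skip_if_not_installed("nortest")
  set.seed(44)
  y <- rchisq(800, df = 1)          # strongly skewed input
  z <- normalize_scores(y)
  expect_gt(nortest::ad.test(z)$p.value, 0.01)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(var(z), 1, tolerance = 0.05)
})

test_that("per-variant logistic GWAS agrees with glm on a random panel", {
  set.seed(45)
  st <- small_study(n = 300, m = 8, seed = 45)
  y <- rbinom(300, 1, plogis(-1 + 0.3 * st$genotypes$dosages[, 1]))
  got <- run_gwas(st$genotypes, y)
  for (j in 1:8) {
    fit <- glm(y ~ st$genotypes$dosages[, j], family = binomial())
    expect_equal(got$beta[j], unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(got$se[j],
                 unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-5)
  }
})

test_that("GWAS recovers a simulated log-odds ratio of 0.3", {
  set.seed(46)
  n <- 5000
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  y <- rbinom(n, 1, plogis(-1.5 + 0.3 * g[, 1]))
  got <- run_gwas(make_geno(g), y)
  expect_lt(abs(got$beta - 0.3), 3 * got$se)
  # null variant: no association
  g0 <- matrix(rbinom(n, 2, 0.4), ncol = 1)
  got0 <- run_gwas(make_geno(g0), y)
  expect_lt(abs(got0$beta), 3 * got0$se)
})

test_that("collapsed 0/2 dosages match the 2x2 closed form", {
  set.seed(47)
  x <- rep(c(0, 2), c(60, 40))
  y <- c(rbinom(60, 1, 0.2), rbinom(40, 1, 0.5))
  tab <- table(x, y)
  log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  se_or <- sqrt(sum(1 / tab))
  got <- run_gwas(make_geno(matrix(x, ncol = 1)), y)
  # dosage coded 0/2: per-dosage-unit effect is half the table log-OR
  expect_equal(got$beta, log_or / 2, tolerance = 1e-6)
  expect_equal(got$se, se_or / 2, tolerance = 1e-6)
})

test_that("separated variants are clamped, flagged and keep a finite p", {
  y <- rep(c(0, 1), each = 20)
  x <- matrix(c(rep(0, 20), rep(2, 20)), ncol = 1)
  got <- run_gwas(make_geno(x), y)
  expect_true(got$flagged)
  expect_lte(abs(got$beta), 10)
  expect_true(is.finite(got$p) && got$p < 0.001)
  expect_error(run_gwas(make_geno(x), rep(1, 40)), "both classes")
})

test_that("meta-analysis matches the closed-form inverse-variance rule", {
  mk <- function(b, s) tibble::tibble(variant_id = "v", beta = b, se = s,
                                      p = 1, flagged = FALSE)
  # symmetry: k identical studies
  m <- meta_analyze(list(mk(0.3, 0.1), mk(0.3, 0.1), mk(0.3, 0.1)))
  expect_equal(m$beta, 0.3)
  expect_equal(m$se, 0.1 / sqrt(3))
  # hand-evaluated two-study case
  m2 <- meta_analyze(list(mk(0.2, 0.1), mk(0.4, 0.2)))
  o <- oracle_meta(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(m2$beta, unname(o["beta"]))
  expect_equal(m2$beta, 0.24)
  expect_equal(m2$se, unname(o["se"]), tolerance = 1e-12)
  expect_equal(m2$se, 0.0894427, tolerance = 1e-6)
  # zero-weight limit
  m3 <- meta_analyze(list(mk(0.2, 0.1), mk(5, Inf)))
  expect_equal(m3$beta, 0.2)
  expect_equal(m3$se, 0.1)
  # precision never worse than the best study
  set.seed(48)
  ses <- runif(4, 0.05, 0.5)
  m4 <- meta_analyze(lapply(ses, function(s) mk(rnorm(1), s)))
  expect_lte(m4$se, min(ses))
  bad <- mk(1, 1)
  bad$variant_id <- "other"
  expect_error(meta_analyze(list(mk(1, 1), bad)), "misaligned")
})

test_that("two-fold LOGO equals a hand-rolled cross-fit oracle", {
  set.seed(49)
  st <- small_study(n = 40, m = 3, seed = 49)
  g <- st$genotypes
  y <- rep(c(0L, 1L), 20)
  got <- logo_prs(g, y, k = 2, seed = 7)
  grp <- attr(got, "groups")
  # oracle: per-group glm GWAS -> single-study weights -> loop PRS
  for (held in 1:2) {
    tr <- which(grp != held)
    betas <- vapply(1:3, function(j) {
      unname(coef(glm(y[tr] ~ g$dosages[tr, j], family = binomial()))[2])
    }, numeric(1))
    expect_true(all(abs(betas) < 10))   # fixture free of separation
    expected <- as.numeric(g$dosages[grp == held, ] %*% betas)
    expect_equal(got$score[grp == held], expected, tolerance = 1e-5)
  }
})

test_that("LOGO scores of a held-out group ignore that group's labels", {
  set.seed(50)
  st <- small_study(n = 120, m = 10, seed = 50)
  y <- rbinom(120, 1, 0.4)
  r1 <- logo_prs(st$genotypes, y, k = 4, seed = 11)
  grp <- attr(r1, "groups")
  held <- which(grp == 1)
  y2 <- y
  y2[held] <- sample(y[held])          # permute labels within group 1 only
  r2 <- logo_prs(st$genotypes, y2, k = 4, seed = 11)
  expect_identical(attr(r2, "groups"), grp)
  expect_equal(r2$score[held], r1$score[held])
})

test_that("LOGO is null-calibrated and recovers heritable signal", {
  set.seed(51)
  # null: phenotype independent of genotypes
  rs <- vapply(1:5, function(s) {
    st <- small_study(n = 400, m = 12, seed = 600 + s)
    y <- rbinom(400, 1, 0.3)
    sc <- logo_prs(st$genotypes, y, k = 4, seed = s)$score
    abs(cor(sc, y))
  }, numeric(1))
  expect_lt(median(rs), 3 / sqrt(400))
  expect_true(all(rs < 6 / sqrt(400)))

  # heritable: 10 causal variants, n = 2000
  wins <- vapply(1:20, function(r) {
    set.seed(700 + r)
    n <- 2000
    m <- 30
    g <- matrix(rbinom(n * m, 2, 0.3), nrow = n)
    beta <- c(rnorm(10, 0, 0.25), rep(0, m - 10))
    y <- rbinom(n, 1, plogis(-1 + as.numeric(g %*% beta)))
    sc <- logo_prs(make_geno(g), y, k = 5, seed = r)$score
    fit <- glm(y ~ scale(sc), family = binomial())
    unname(coef(fit)[2]) > 0
  }, logical(1))
  expect_gte(sum(wins), 19)
})
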
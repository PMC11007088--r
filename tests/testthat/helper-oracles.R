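# Independent oracles: brute-force enumerations and closed forms kept
# deliberately separate from the package's computational paths.

# Harrell's C by exhaustive O(n^2) pair enumeration
oracle_cindex <- function(score, time, event) {
  n <- length(score)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (event[i] == 1 && time[i] < time[j]) ||
        (event[i] == 1 && time[i] == time[j] && event[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  num / den
}

# product-limit estimator by direct looping over distinct event times
oracle_km <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Efron-approximation Cox log partial likelihood, single covariate
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    theta_r <- sum(exp(beta * x[r_idx]))
    theta_d <- sum(exp(beta * x[d_idx]))
    ll <- ll + beta * sum(x[d_idx])
    for (l in seq_len(d) - 1)
      ll <- ll - log(theta_r - (l / d) * theta_d)
  }
  ll
}

oracle_cox_beta <- function(time, event, x, lim = c(-5, 5)) {
  stats::optimize(oracle_efron_loglik, lim, time = time, event = event,
                  x = x, maximum = TRUE, tol = 1e-10)$maximum
}

# per-sample, per-variant double loop PRS with allele resolution
oracle_prs <- function(dosages, geno_variants, panel) {
  n <- nrow(dosages)
  score <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(nrow(panel))) {
      j <- which(geno_variants$variant_id == panel$variant_id[k])
      if (!length(j)) next
      d <- dosages[i, j]
      if (is.na(d)) d <- mean(dosages[, j], na.rm = TRUE)
      if (panel$effect_allele[k] == geno_variants$effect_allele[j])
        score[i] <- score[i] + panel$weight[k] * d
      else if (panel$effect_allele[k] == geno_variants$other_allele[j])
        score[i] <- score[i] + panel$weight[k] * (2 - d)
    }
  }
  score
}

oracle_meta <- function(betas, ses) {
  w <- 1 / ses^2
  b <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  c(beta = b, se = se, p = 2 * pnorm(-abs(b / se)))
}

# small genotype fixture straight from a dosage matrix
make_geno <- function(dosages, effect_allele = "A", other_allele = "G") {
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("S%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("v%03d", seq_len(ncol(dosages)))
  m <- ncol(dosages)
  genotype_matrix(dosages, tibble::tibble(
    variant_id = colnames(dosages), chrom = 1L, pos = seq_len(m),
    effect_allele = effect_allele, other_allele = other_allele,
    maf = pmin(colMeans(dosages, na.rm = TRUE) / 2,
               1 - colMeans(dosages, na.rm = TRUE) / 2),
    call_rate = 1 - colMeans(is.na(dosages)),
    hwe_p = 1, info = 1))
}

small_study <- function(n = 600, m = 60, seed = 1, preset = "table1", ...) {
  generate_study(preset_params(preset, n_samples = n, n_variants = m,
                               n_causal_per_trait = min(10L, m),
                               seed = seed, ...))
}
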
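#' Quality-control thresholds
#'
#' Defaults follow common SNP-array practice: samples dropped below 97%
#' call rate or with heterozygosity more than 3 SD from the cohort mean;
#' variants dropped below 95% call rate, Hardy-Weinberg equilibrium
#' p < 1e-6, minor allele frequency < 1%, or imputation quality < 0.8.
#' Comparisons are strict "<" exclusions, so a value exactly at a
#' threshold survives.
#'
#' @param sample_call_rate_min,variant_call_rate_min minimum call rates.
#' @param hwe_p_min minimum HWE p-value.
#' @param maf_min minimum minor allele frequency.
#' @param info_min minimum imputation quality.
#' @param het_outlier_sd half-width, in SDs, of the heterozygosity band.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.97,
                          variant_call_rate_min = 0.95,
                          hwe_p_min = 1e-6,
                          maf_min = 0.01,
                          info_min = 0.8,
                          het_outlier_sd = 3) {
  fr <- c(sample_call_rate_min, variant_call_rate_min, maf_min)
  if (any(fr < 0 | fr > 1) || hwe_p_min < 0 || hwe_p_min > 1)
    abort("qc_thresholds: rates and probabilities must lie in [0, 1]")
  if (het_outlier_sd <= 0) abort("qc_thresholds: het_outlier_sd must be > 0")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 variant_call_rate_min = variant_call_rate_min,
                 hwe_p_min = hwe_p_min, maf_min = maf_min,
                 info_min = info_min, het_outlier_sd = het_outlier_sd),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the expectations `p^2 : 2pq : q^2` at the empirical allele
#' frequency. Returns `p = 1` when the allele frequency is 0 or 1 (the
#' heterozygote and one homozygote class are then structurally empty, so
#' no departure is testable). Vectorized over the three count vectors.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return HWE p-value(s) in \[0, 1\].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("hwe_test: counts must be >= 0")
  if (any(n == 0)) abort("hwe_test: all-zero genotype counts")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  exp_AA <- n * p^2
  exp_Aa <- n * 2 * p * q
  exp_aa <- n * q^2
  stat <- ifelse(p == 0 | q == 0, 0,
                 (n_AA - exp_AA)^2 / pmax(exp_AA, .Machine$double.xmin) +
                 (n_Aa - exp_Aa)^2 / pmax(exp_Aa, .Machine$double.xmin) +
                 (n_aa - exp_aa)^2 / pmax(exp_aa, .Machine$double.xmin))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

qc_report <- function(axis, counts, n_in, surviving) {
  structure(list(axis = axis,
                 counts = tibble::tibble(filter = names(counts),
                                         n_removed = unname(counts)),
                 n_input = n_in, n_removed = n_in - length(surviving),
                 surviving = surviving,
                 notes = character()),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report:%s> %d in, %d removed, %d kept\n", x$axis,
              x$n_input, x$n_removed, length(x$surviving)))
  print(x$counts)
  for (nt in x$notes) cat(" note:", nt, "\n")
  invisible(x)
}

#' Filter variants on call rate, HWE, MAF and imputation quality
#'
#' Retains exactly the variants with `call_rate >= variant_call_rate_min`,
#' `hwe_p >= hwe_p_min`, `maf >= maf_min` and `info >= info_min`
#' (strict "<" exclusions), preserving variant order. Per-filter counts
#' in the report count each criterion independently, so a variant failing
#' two filters appears in both counts but is removed once.
#'
#' @param geno a [genotype_matrix()] with metadata columns `call_rate`,
#'   `hwe_p`, `maf`, `info`.
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with elements `genotypes` (filtered) and `report`
#'   (a `qc_report`).
#' @export
filter_variants <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  v <- geno$variants
  for (col in c("call_rate", "hwe_p", "maf", "info"))
    if (!col %in% names(v))
      abort(paste0("filter_variants: missing metadata column '", col, "'"))
  fail <- list(
    call_rate = v$call_rate < thresholds$variant_call_rate_min,
    hwe = v$hwe_p < thresholds$hwe_p_min,
    maf = v$maf < thresholds$maf_min,
    info = v$info < thresholds$info_min)
  keep <- !Reduce(`|`, fail)
  out <- genotype_matrix(geno$dosages[, keep, drop = FALSE],
                         v[keep, , drop = FALSE])
  rep <- qc_report("variants", vapply(fail, sum, integer(1)),
                   nrow(v), v$variant_id[keep])
  list(genotypes = out, report = rep)
}

#' Filter samples on call rate and heterozygosity
#'
#' Removes samples whose call rate (share of non-missing dosages) falls
#' below `sample_call_rate_min` and samples whose heterozygosity rate
#' (share of dosage-1 calls among non-missing) lies more than
#' `het_outlier_sd` SDs from the cohort mean. Sex-discrepancy,
#' relatedness and ancestry-outlier checks are out of scope here and the
#' report says so.
#'
#' @inheritParams filter_variants
#' @return A list with `genotypes` and `report`, as [filter_variants()].
#' @export
filter_samples <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  d <- geno$dosages
  if (nrow(d) < 2)
    abort("filter_samples: need >= 2 samples for the heterozygosity filter")
  call_rate <- 1 - rowMeans(is.na(d))
  het <- rowSums(round(d) == 1, na.rm = TRUE) / pmax(rowSums(!is.na(d)), 1)
  mu <- mean(het)
  s <- sd(het)
  fail <- list(
    call_rate = call_rate < thresholds$sample_call_rate_min,
    heterozygosity = if (s > 0)
      abs(het - mu) > thresholds$het_outlier_sd * s
    else rep(FALSE, nrow(d)))
  keep <- !Reduce(`|`, fail)
  out <- genotype_matrix(d[keep, , drop = FALSE], geno$variants)
  rep <- qc_report("samples", vapply(fail, sum, integer(1)),
                   nrow(d), rownames(d)[keep])
  rep$notes <- paste("sex-discrepancy, relatedness and PCA-outlier checks",
                     "not performed (out of scope)")
  list(genotypes = out, report = rep)
}
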
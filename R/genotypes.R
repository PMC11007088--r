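#' Construct a genotype matrix object
#'
#' A light container for dosage data: a samples-by-variants numeric matrix
#' (values in \[0, 2\], `NA` = missing call) plus a variant metadata tibble.
#'
#' @param dosages numeric matrix, rows = samples (rownames = sample ids),
#'   columns = variants (colnames = variant ids).
#' @param variants tibble with one row per column of `dosages`: columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `maf`,
#'   `call_rate`, `hwe_p`, `info`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants),
            ncol(dosages) == nrow(variants))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    abort("genotype_matrix: dosages must carry sample and variant names")
  if (!identical(colnames(dosages), variants$variant_id))
    abort("genotype_matrix: variant metadata must align with dosage columns")
  structure(list(dosages = dosages, variants = tibble::as_tibble(variants)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

variant_metadata <- function(dosages, chrom = 1L, info = NULL) {
  n <- nrow(dosages)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  call_rate <- 1 - colMeans(is.na(dosages))
  hwe <- vapply(seq_len(ncol(dosages)), function(j) {
    d <- dosages[, j]
    d <- d[!is.na(d)]
    g <- round(d)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  tibble::tibble(
    variant_id = colnames(dosages),
    chrom = chrom, pos = seq_len(ncol(dosages)) * 1000L,
    effect_allele = "A", other_allele = "G",
    maf = maf, call_rate = call_rate, hwe_p = hwe,
    info = info %||% rep(1, ncol(dosages)))
}

#' Simulate a genotype dosage panel
#'
#' Draws hard-call dosages `binomial(2, maf)` per variant (variants
#' mutually independent, no linkage disequilibrium) and populates the
#' variant metadata: empirical allele frequency, call rate,
#' Hardy-Weinberg equilibrium p-value and a simulated imputation-quality
#' score. An optional corruption profile plants known quality-control
#' violations so each filter can be exercised:
#'
#' * `n_low_maf` variants redrawn at MAF 0.002 (fails the 1% MAF filter);
#' * `n_hwe_fail` variants rewritten with a strong heterozygote deficit;
#' * `n_low_info` variants given imputation quality 0.5;
#' * `n_low_call_variants` variants with 10% of calls set missing;
#' * `n_low_call_samples` samples with 5% of calls set missing;
#' * `n_het_outlier` samples with all non-missing dosages set
#'   heterozygous (inflated heterozygosity).
#'
#' Corrupted items use the first variants/samples, in the order above, so
#' tests know exactly which ids must fail.
#'
#' @param params a [sim_params()] object (`corruption` field optional).
#' @return A [genotype_matrix()].
#' @export
sample_genotypes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_samples
  m <- params$n_variants
  maf <- runif(m, params$maf_range[1], params$maf_range[2])
  dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  rownames(dos) <- sprintf("S%05d", seq_len(n))
  colnames(dos) <- sprintf("var%05d", seq_len(m))
  info <- runif(m, 0.85, 1)

  cor <- params$corruption
  if (!is.null(cor)) {
    v_at <- 0L
    take_v <- function(k) {
      idx <- v_at + seq_len(k)
      v_at <<- v_at + k
      idx
    }
    if ((k <- cor$n_low_maf %||% 0L) > 0) {
      idx <- take_v(k)
      dos[, idx] <- rbinom(n * k, 2L, 0.002)
    }
    if ((k <- cor$n_hwe_fail %||% 0L) > 0) {
      idx <- take_v(k)
      # equal homozygote mix, no heterozygotes: chi-square ~ n
      dos[, idx] <- sample(c(0L, 2L), n * k, replace = TRUE)
    }
    if ((k <- cor$n_low_info %||% 0L) > 0) info[take_v(k)] <- 0.5
    if ((k <- cor$n_low_call_variants %||% 0L) > 0) {
      idx <- take_v(k)
      for (j in idx) dos[sample.int(n, ceiling(0.10 * n)), j] <- NA
    }
    if ((k <- cor$n_low_call_samples %||% 0L) > 0) {
      for (i in seq_len(k)) dos[i, sample.int(m, ceiling(0.05 * m))] <- NA
    }
    if ((k <- cor$n_het_outlier %||% 0L) > 0) {
      rows <- (cor$n_low_call_samples %||% 0L) + seq_len(k)
      for (i in rows) dos[i, !is.na(dos[i, ])] <- 1L
    }
  }
  genotype_matrix(dos, variant_metadata(dos, info = info))
}

# ---- readers / writers ------------------------------------------------

#' Read or write dosage data as plain TSV
#'
#' The dosage table is samples x variants with a leading `sample_id`
#' column; variant metadata travels in a second TSV. Missing dosages are
#' empty fields.
#'
#' @param geno a `genotype_matrix`.
#' @param dosage_path,variant_path file paths for the two tables.
#' @return `write_dosage_tsv()` returns the paths invisibly;
#'   `read_dosage_tsv()` returns a `genotype_matrix`.
#' @export
write_dosage_tsv <- function(geno, dosage_path, variant_path) {
  d <- tibble::as_tibble(geno$dosages)
  d <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(geno$dosages)), d)
  readr::write_tsv(d, dosage_path)
  readr::write_tsv(geno$variants, variant_path)
  invisible(c(dosage_path, variant_path))
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(dosage_path, variant_path) {
  d <- readr::read_tsv(dosage_path, show_col_types = FALSE)
  v <- readr::read_tsv(variant_path, show_col_types = FALSE,
                       col_types = readr::cols(
                         variant_id = "c", effect_allele = "c",
                         other_allele = "c", .default = readr::col_guess()))
  m <- as.matrix(d[setdiff(names(d), "sample_id")])
  rownames(m) <- d$sample_id
  genotype_matrix(m, v)
}

#' Write dosages as a VCF with a DS FORMAT field
#'
#' Emits a minimal VCFv4.2 file carrying one `DS` (alternate-allele
#' dosage) value per sample and genotype set to `./.`; the effect allele
#' is written as ALT so dosages count it directly.
#'
#' @param geno a `genotype_matrix`.
#' @param path output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf_dosage <- function(geno, path) {
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosages)), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- geno$dosages[, j]
    ds <- ifelse(is.na(ds), ".", format(ds, trim = TRUE))
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "DS", ds),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read and write per-trait weight panels
#'
#' A weight panel is a TSV with columns `variant_id`, `effect_allele`,
#' `weight` — the additive per-allele effect used by [compute_prs()].
#'
#' @param panel tibble with the three columns above.
#' @param path file path.
#' @return `write_weight_panel()` the path invisibly; `read_weight_panel()`
#'   the panel tibble.
#' @export
write_weight_panel <- function(panel, path) {
  stopifnot(all(c("variant_id", "effect_allele", "weight") %in% names(panel)))
  readr::write_tsv(panel[c("variant_id", "effect_allele", "weight")], path)
  invisible(path)
}

#' @rdname write_weight_panel
#' @export
read_weight_panel <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(variant_id = "c",
                                          effect_allele = "c", weight = "d"))
}
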
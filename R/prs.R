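#' Compute an additive polygenic risk score
#'
#' `score_i = sum_v dosage_iv * weight_v`, where the dosage counts the
#' panel's effect allele. When the genotype panel's coded allele is the
#' weight panel's *other* allele the dosage is flipped to `2 - d`; when
#' neither allele matches, the variant is skipped with a warning count.
#' Panel variants absent from the genotypes are skipped and counted.
#' Missing dosages are mean-imputed as twice the variant's allele
#' frequency (the usual scoring convention).
#'
#' @param geno a [genotype_matrix()].
#' @param panel weight panel tibble: `variant_id`, `effect_allele`,
#'   `weight`.
#' @param trait optional trait label stored in the output.
#' @return A tibble `sample_id`, `trait`, `score` with attributes
#'   `n_variants_used`, `n_missing`, `n_flipped`, `n_mismatched`.
#' @export
compute_prs <- function(geno, panel, trait = NA_character_) {
  stopifnot(inherits(geno, "genotype_matrix"),
            all(c("variant_id", "effect_allele", "weight") %in% names(panel)))
  v <- geno$variants
  pos <- match(panel$variant_id, v$variant_id)
  present <- !is.na(pos)
  n_missing <- sum(!present)
  if (!any(present))
    abort("compute_prs: no panel variant overlaps the genotype panel")
  pos <- pos[present]
  pw <- panel[present, ]
  same <- pw$effect_allele == v$effect_allele[pos]
  flip <- !same & pw$effect_allele == v$other_allele[pos]
  mism <- !same & !flip
  if (any(mism))
    warn(sprintf("compute_prs: %d variant(s) skipped for allele mismatch",
                 sum(mism)))
  use <- which(!mism)
  if (!length(use))
    abort("compute_prs: no allele-consistent panel variant overlaps")
  d <- geno$dosages[, pos[use], drop = FALSE]
  if (anyNA(d)) {
    af2 <- colMeans(d, na.rm = TRUE)
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- af2[na_idx[, 2]]
  }
  w <- pw$weight[use]
  fl <- flip[use]
  # flipped variants: w * (2 - d) = 2w - w*d
  score <- as.numeric(d %*% ifelse(fl, -w, w)) + 2 * sum(w[fl])
  out <- tibble::tibble(sample_id = rownames(geno$dosages),
                        trait = trait, score = score)
  attr(out, "n_variants_used") <- length(use)
  attr(out, "n_missing") <- n_missing
  attr(out, "n_flipped") <- sum(fl)
  attr(out, "n_mismatched") <- sum(mism)
  out
}

#' Normalize scores to a normal distribution
#'
#' Default is the rank-based inverse-normal transform with Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`. The result is a monotone transform
#' of the input with near-zero mean, near-unit variance and
#' normal-quantile marginals. `"zscore"` plain standardization is
#' available as an alternative.
#'
#' @param x numeric vector, `n >= 2`, non-constant.
#' @param method `"inverse_normal"` (default) or `"zscore"`.
#' @return Numeric vector of normalized scores.
#' @export
normalize_scores <- function(x, method = c("inverse_normal", "zscore")) {
  method <- match.arg(method)
  if (length(x) < 2) abort("normalize_scores: need n >= 2")
  if (any(!is.finite(x))) abort("normalize_scores: scores must be finite")
  if (sd(x) == 0) abort("normalize_scores: constant input")
  if (method == "zscore") return(as.numeric(scale(x)))
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Per-variant logistic GWAS
#'
#' Univariate logistic regression of a binary phenotype on each variant's
#' dosage (intercept + dosage), fitted by iteratively reweighted least
#' squares vectorized across variants; reports the Wald effect size,
#' standard error and p-value per variant. Monomorphic variants get
#' `beta = 0`, `se = Inf`, `p = 1`. When a fit separates (|beta|
#' diverging), the effect is clamped at |beta| = 10, flagged, and the
#' p-value replaced by the Rao score test at beta = 0, which stays
#' finite under separation. Missing dosages are mean-imputed per variant.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno 0/1 phenotype vector, both classes present.
#' @param max_iter,tol IRLS controls.
#' @return A tibble `variant_id`, `beta`, `se`, `p`, `flagged`.
#' @export
run_gwas <- function(geno, pheno, max_iter = 30L, tol = 1e-8) {
  stopifnot(inherits(geno, "genotype_matrix"))
  pheno <- as.integer(pheno)
  if (length(pheno) != nrow(geno$dosages))
    abort("run_gwas: phenotype length must match sample count")
  if (length(unique(pheno)) < 2)
    abort("run_gwas: phenotype must contain both classes")
  G <- geno$dosages
  if (anyNA(G)) {
    af2 <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- af2[idx[, 2]]
  }
  n <- nrow(G)
  m <- ncol(G)
  y <- pheno
  poly <- apply(G, 2, sd) > 0
  b0 <- rep(qlogis(mean(y)), m)
  b1 <- rep(0, m)
  clamp <- 10
  for (it in seq_len(max_iter)) {
    eta <- rep(b0, each = n) + G * rep(b1, each = n)
    dim(eta) <- dim(G)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    # per-variant 2x2 weighted normal equations
    Sw <- colSums(w)
    Swx <- colSums(w * G)
    Swxx <- colSums(w * G * G)
    U0 <- colSums(r)
    U1 <- colSums(r * G)
    det <- Sw * Swxx - Swx^2
    ok <- poly & det > 1e-12
    d0 <- ifelse(ok, (Swxx * U0 - Swx * U1) / det, 0)
    d1 <- ifelse(ok, (Sw * U1 - Swx * U0) / det, 0)
    b0 <- b0 + d0
    b1 <- b1 + d1
    b1 <- pmin(pmax(b1, -clamp), clamp)
    if (max(abs(c(d0, d1))) < tol) break
  }
  eta <- rep(b0, each = n) + G * rep(b1, each = n)
  dim(eta) <- dim(G)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  Sw <- colSums(w)
  Swx <- colSums(w * G)
  Swxx <- colSums(w * G * G)
  det <- Sw * Swxx - Swx^2
  se <- ifelse(poly & det > 1e-12, sqrt(Sw / pmax(det, 1e-300)), Inf)
  flagged <- poly & abs(b1) >= clamp - 1e-6
  zstat <- b1 / se
  p <- 2 * pnorm(-abs(zstat))
  if (any(flagged)) {
    # score test at beta = 0: U^2 / V with null fitted probabilities
    mu0 <- mean(y)
    U <- colSums((y - mu0) * G)
    xbar <- colMeans(G)
    V <- mu0 * (1 - mu0) * (colSums(G * G) - n * xbar^2)
    p_score <- pchisq(U^2 / pmax(V, 1e-300), df = 1, lower.tail = FALSE)
    p[flagged] <- p_score[flagged]
  }
  p[!poly] <- 1
  b1[!poly] <- 0
  tibble::tibble(variant_id = geno$variants$variant_id,
                 beta = unname(b1), se = unname(se), p = unname(p),
                 flagged = unname(flagged))
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines aligned per-variant association results:
#' `beta = sum(beta_k / se_k^2) / sum(1 / se_k^2)`,
#' `se = sqrt(1 / sum(1 / se_k^2))`, p from the normal Wald statistic.
#' Infinite standard errors contribute zero weight.
#'
#' @param results list (>= 2) of GWAS tibbles with identical
#'   `variant_id` ordering.
#' @return A tibble `variant_id`, `beta`, `se`, `p`.
#' @export
meta_analyze <- function(results) {
  if (length(results) < 2) abort("meta_analyze: need >= 2 result sets")
  ids <- results[[1]]$variant_id
  for (r in results[-1])
    if (!identical(r$variant_id, ids))
      abort("meta_analyze: variant ids are misaligned across result sets")
  W <- vapply(results, function(r) 1 / r$se^2, numeric(length(ids)))
  B <- vapply(results, function(r) r$beta, numeric(length(ids)))
  if (!is.matrix(W)) {
    W <- matrix(W, nrow = 1)
    B <- matrix(B, nrow = 1)
  }
  W[!is.finite(W)] <- 0
  sw <- rowSums(W)
  beta <- rowSums(W * B) / pmax(sw, .Machine$double.xmin)
  se <- 1 / sqrt(pmax(sw, .Machine$double.xmin))
  beta[sw == 0] <- 0
  se[sw == 0] <- Inf
  tibble::tibble(variant_id = ids, beta = beta, se = se,
                 p = 2 * pnorm(-abs(beta / se)))
}

#' Leave-one-group-out cross-fit polygenic score
#'
#' Implements the leakage-free cross-fitting scheme: samples are randomly
#' partitioned into `k` groups; each group's scores are computed with
#' weights estimated *only* from the other `k - 1` groups — per-group
#' GWAS ([run_gwas()]), inverse-variance meta-analysis of the held-out
#' group's complement ([meta_analyze()]), and a p-value-thresholded
#' marginal-weight rule (meta beta where meta p <= `p_threshold`, else
#' 0; the default 1 keeps every variant). The weighting rule is the
#' `weight_fun(meta)` argument, so externally produced shrinkage weights
#' can be slotted in.
#'
#' @param geno a [genotype_matrix()].
#' @param pheno 0/1 phenotype with both classes present in every group
#'   (the partition is redrawn up to `max_retry` times otherwise).
#' @param k number of groups (>= 2).
#' @param p_threshold meta-analysis p-value cutoff for nonzero weights.
#' @param weight_fun optional function `meta_tibble -> numeric weights`.
#' @param seed optional seed for the partition.
#' @param max_retry partition redraw limit.
#' @return A tibble `sample_id`, `score` with attribute `groups` (the
#'   partition) and `trait` column `"LOGO"`.
#' @export
logo_prs <- function(geno, pheno, k = 10L, p_threshold = 1,
                     weight_fun = NULL, seed = NULL, max_retry = 20L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (k < 2) abort("logo_prs: k must be >= 2")
  n <- nrow(geno$dosages)
  pheno <- as.integer(pheno)
  if (length(pheno) != n) abort("logo_prs: phenotype length mismatch")
  if (!is.null(seed)) set.seed(seed)
  grp <- NULL
  for (try in seq_len(max_retry)) {
    g <- sample(rep_len(seq_len(k), n))
    ok <- all(vapply(seq_len(k), function(i) {
      ph <- pheno[g == i]
      length(unique(ph)) == 2
    }, logical(1)))
    if (ok) {
      grp <- g
      break
    }
  }
  if (is.null(grp)) {
    sizes <- table(sample(rep_len(seq_len(k), n)))
    abort(paste0("logo_prs: a group lacked both phenotype classes after ",
                 max_retry, " redraws (group sizes ~", toString(sizes), ")"))
  }
  if (is.null(weight_fun))
    weight_fun <- function(meta) ifelse(meta$p <= p_threshold, meta$beta, 0)
  subset_geno <- function(rows)
    genotype_matrix(geno$dosages[rows, , drop = FALSE], geno$variants)
  # one GWAS per group; each held-out group then meta-analyzes the rest
  gwas_by_group <- lapply(seq_len(k), function(i)
    run_gwas(subset_geno(grp == i), pheno[grp == i]))
  score <- numeric(n)
  for (i in seq_len(k)) {
    rest <- gwas_by_group[-i]
    meta <- if (length(rest) == 1) rest[[1]] else meta_analyze(rest)
    panel <- tibble::tibble(variant_id = geno$variants$variant_id,
                            effect_allele = geno$variants$effect_allele,
                            weight = weight_fun(meta))
    held <- which(grp == i)
    score[held] <- compute_prs(subset_geno(held), panel)$score
  }
  out <- tibble::tibble(sample_id = rownames(geno$dosages),
                        trait = "LOGO", score = score)
  attr(out, "groups") <- grp
  out
}
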
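#' Fit combination weights for several trait PRSs
#'
#' One multiple logistic regression of prevalent disease status on all
#' included normalized trait scores plus age and sex; the per-trait
#' coefficients (log-odds per unit score) are the combination weights
#' used by [combine_wprssum()]. Covariate coefficients are retained for
#' reporting but never enter the weighted sum.
#'
#' @param data tibble with one column per trait score plus the outcome
#'   and covariate columns.
#' @param traits names of the trait score columns.
#' @param prevalent,age,sex column names of the outcome (0/1), age and
#'   sex (`"male"`/`"female"`).
#' @return An object of class `prs_weight_fit` with [tidy()] and
#'   [glance()] methods.
#' @export
fit_prs_weights <- function(data, traits,
                            prevalent = "prevalent_cvd",
                            age = "age", sex = "sex") {
  miss <- setdiff(c(traits, prevalent, age, sex), names(data))
  if (length(miss))
    abort(paste0("fit_prs_weights: missing column(s) ", toString(miss)))
  y <- data[[prevalent]]
  if (sum(y == 1) < 1 || sum(y == 0) < 1)
    abort("fit_prs_weights: need at least one case and one non-case")
  df <- data.frame(.y = y,
                   data[traits],
                   .age = data[[age]],
                   .male = as.integer(data[[sex]] == "male"),
                   check.names = FALSE)
  f <- as.formula(paste0(".y ~ ", paste(c(sprintf("`%s`", traits),
                                          ".age", ".male"), collapse = " + ")))
  fit <- suppressWarnings(glm(f, family = binomial(), data = df))
  if (!fit$converged || any(abs(coef(fit)[traits]) > 15, na.rm = TRUE))
    abort(paste("fit_prs_weights: logistic fit separated;",
                "a larger cohort is needed to weight the scores"))
  cf <- summary(fit)$coefficients
  wt <- tibble::tibble(trait = traits,
                       weight = cf[traits, "Estimate"],
                       se = cf[traits, "Std. Error"],
                       p = cf[traits, "Pr(>|z|)"])
  structure(list(weights = wt,
                 covariates = tibble::tibble(
                   term = c("(Intercept)", "age", "male"),
                   estimate = cf[c("(Intercept)", ".age", ".male"),
                                 "Estimate"]),
                 n_cases = sum(y == 1), n_total = length(y),
                 fit = fit),
            class = "prs_weight_fit")
}

#' @export
print.prs_weight_fit <- function(x, ...) {
  cat(sprintf("<prs_weight_fit> %d traits, %d cases / %d samples\n",
              nrow(x$weights), x$n_cases, x$n_total))
  print(x$weights)
  invisible(x)
}

#' @rdname fit_prs_weights
#' @param x a `prs_weight_fit` object.
#' @param ... unused.
#' @method tidy prs_weight_fit
#' @export
tidy.prs_weight_fit <- function(x, ...) {
  dplyr::transmute(x$weights, term = .data$trait, estimate = .data$weight,
                   std.error = .data$se, p.value = .data$p)
}

#' @rdname fit_prs_weights
#' @method glance prs_weight_fit
#' @export
glance.prs_weight_fit <- function(x, ...) {
  tibble::tibble(n_traits = nrow(x$weights), n_cases = x$n_cases,
                 n_total = x$n_total,
                 deviance = x$fit$deviance, aic = x$fit$aic)
}

#' Combine trait scores into a weighted PRS sum
#'
#' `wprssum_i = sum_t weight_t * score_it` over the traits in the fit;
#' the fit's intercept and covariate coefficients are excluded.
#'
#' @param data tibble containing one column per trait in `fit`.
#' @param fit a [fit_prs_weights()] object.
#' @return `data` with a new `wprssum` column.
#' @export
combine_wprssum <- function(data, fit) {
  stopifnot(inherits(fit, "prs_weight_fit"))
  miss <- setdiff(fit$weights$trait, names(data))
  if (length(miss))
    abort(paste0("combine_wprssum: missing trait column(s) ", toString(miss)))
  M <- as.matrix(data[fit$weights$trait])
  dplyr::mutate(data, wprssum = as.numeric(M %*% fit$weights$weight))
}

#' Assign low / intermediate / high genetic risk groups
#'
#' Cutpoints are the `cut_low` and `cut_high` empirical quantiles
#' (type-7 linear interpolation) of the score over the `base` set —
#' by default the full table, but the base may be a superset rule (e.g.
#' all genotyped samples before exclusions) applied to a subset, in
#' which case subset group sizes are near, not exactly, the nominal
#' fractions. Intervals are `[min, q_low)`, `[q_low, q_high)`,
#' `[q_high, max]`: a score equal to a cutpoint falls in the upper group.
#'
#' @param data tibble with the score column.
#' @param score score column name (default `"wprssum"`).
#' @param cut_low,cut_high quantile cutpoints (defaults 0.20 / 0.80).
#' @param base optional numeric vector of scores defining the cutpoints;
#'   default the score column itself.
#' @return `data` with a `genetic_group` factor (levels `low`,
#'   `intermediate`, `high`); cutpoints in attribute `cutpoints`.
#' @export
assign_genetic_groups <- function(data, score = "wprssum",
                                  cut_low = 0.20, cut_high = 0.80,
                                  base = NULL) {
  if (!score %in% names(data))
    abort(paste0("assign_genetic_groups: missing column '", score, "'"))
  base <- base %||% data[[score]]
  if (!length(base)) abort("assign_genetic_groups: empty base set")
  q <- quantile(base, c(cut_low, cut_high), type = 7, names = FALSE)
  if (q[1] == q[2])
    abort("assign_genetic_groups: degenerate score distribution (q_low = q_high)")
  x <- data[[score]]
  g <- dplyr::case_when(x < q[1] ~ "low",
                        x < q[2] ~ "intermediate",
                        TRUE ~ "high")
  out <- dplyr::mutate(data, genetic_group = factor(
    g, levels = c("low", "intermediate", "high")))
  attr(out, "cutpoints") <- q
  out
}

#' Association scan over every trait subset
#'
#' For each nonempty subset of the traits, fits the logistic weighting
#' model on that subset, forms the subset's weighted score sum, and
#' reports the age/sex-adjusted odds ratio per SD of that sum against
#' prevalent disease from a second logistic fit (so rows with different
#' subset sizes are on a comparable scale). Four traits give the full
#' 15-row scan.
#'
#' @inheritParams fit_prs_weights
#' @return A tibble `subset`, `n_traits`, `odds_ratio`, `p`.
#' @export
prs_association_scan <- function(data, traits,
                                 prevalent = "prevalent_cvd",
                                 age = "age", sex = "sex") {
  subsets <- unlist(lapply(seq_along(traits), function(k)
    utils::combn(traits, k, simplify = FALSE)), recursive = FALSE)
  purrr::map_dfr(subsets, function(tr) {
    fit <- fit_prs_weights(data, tr, prevalent, age, sex)
    comb <- combine_wprssum(data, fit)
    z <- as.numeric(scale(comb$wprssum))
    df <- data.frame(.y = data[[prevalent]], z = z,
                     .age = data[[age]],
                     .male = as.integer(data[[sex]] == "male"))
    g <- glm(.y ~ z + .age + .male, family = binomial(), data = df)
    cf <- summary(g)$coefficients
    tibble::tibble(subset = paste(tr, collapse = " + "),
                   n_traits = length(tr),
                   odds_ratio = exp(cf["z", "Estimate"]),
                   p = cf["z", "Pr(>|z|)"])
  })
}
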
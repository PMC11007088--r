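#' Apply baseline exclusions
#'
#' Removes prevalent-disease participants and participants missing any
#' clinical covariate of the risk equation; the remainder is the
#' incident-analysis set. Exclusion reasons are counted in order
#' (prevalent first, then missing), so each removed row has one reason
#' and counts reconcile exactly with the input size.
#'
#' @param cohort tibble with `prevalent_cvd` and the clinical covariate
#'   columns.
#' @return A list: `data` (analysis set), `report` (tibble
#'   `reason`, `n`, including a `retained` row).
#' @export
apply_exclusions <- function(cohort) {
  need <- c("prevalent_cvd", "sex", "age", "tc", "hdl", "sbp",
            "bp_treated", "smoker", "diabetes")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    abort(paste0("apply_exclusions: missing column(s) ", toString(miss)))
  prevalent <- cohort$prevalent_cvd == 1
  covar_missing <- !complete.cases(cohort[setdiff(need, "prevalent_cvd")])
  missing_only <- covar_missing & !prevalent
  keep <- !prevalent & !covar_missing
  if (!any(keep)) abort("apply_exclusions: no samples remain")
  list(data = cohort[keep, ],
       report = tibble::tibble(
         reason = c("prevalent_cvd", "missing_covariate", "retained"),
         n = c(sum(prevalent), sum(missing_only), sum(keep))))
}

#' Cross-classify clinical and genetic risk groups
#'
#' Combines the two-level clinical (`pce_group`) and three-level genetic
#' (`genetic_group`) labels into a six-level stratum factor ordered
#' low-to-high joint risk, with baseline `pce low / genetic low`.
#'
#' @param data tibble carrying both group columns.
#' @return `data` with a `stratum` factor.
#' @export
combine_strata <- function(data) {
  miss <- setdiff(c("pce_group", "genetic_group"), names(data))
  if (length(miss))
    abort(paste0("combine_strata: missing column(s) ", toString(miss)))
  lev <- as.vector(outer(c("low", "intermediate", "high"),
                         c("low", "high"),
                         function(g, p) paste0("pce_", p, "/prs_", g)))
  s <- paste0("pce_", data$pce_group, "/prs_", data$genetic_group)
  dplyr::mutate(data, stratum = factor(s, levels = lev))
}

#' Stratum hazard-ratio table
#'
#' Fits one age/sex-adjusted Cox model with the stratum factor (baseline
#' = lowest joint stratum) and reports, per stratum, its size, event
#' count and the stratum-indicator hazard ratio with SE and Wald p.
#' Empty strata are kept as rows with missing estimates, with a warning.
#'
#' @param data tibble with `stratum` and follow-up/covariate columns.
#' @param adjust covariates to adjust for (default age and sex).
#' @param time,event follow-up column names.
#' @return A tibble of class `stratum_table`: `pce_group`,
#'   `genetic_group`, `n`, `n_events`, `hazard_ratio`, `se`, `p`.
#' @export
stratum_cox <- function(data, adjust = c("age", "sex"),
                        time = "time_years", event = "event") {
  if (!"stratum" %in% names(data))
    abort("stratum_cox: missing 'stratum' column (see combine_strata)")
  counts <- data |>
    dplyr::count(.data$stratum, .drop = FALSE, name = "n") |>
    dplyr::left_join(
      data |>
        dplyr::filter(.data[[event]] == 1) |>
        dplyr::count(.data$stratum, .drop = FALSE, name = "n_events"),
      by = "stratum") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  empty <- counts$stratum[counts$n == 0]
  if (length(empty))
    warn(paste0("stratum_cox: empty stratum(s) ", toString(empty),
                "; hazard ratios marked missing"))
  d <- dplyr::mutate(data, stratum = droplevels(.data$stratum))
  fit <- fit_cox(d, c("stratum", adjust), time = time, event = event)
  td <- tidy(fit)
  td <- td[grepl("^stratum", td$term), ]
  td$stratum <- sub("^stratum", "", td$term)
  out <- counts |>
    dplyr::left_join(td[c("stratum", "hazard_ratio", "std.error", "p.value")],
                     by = c(stratum = "stratum")) |>
    dplyr::mutate(
      pce_group = sub("^pce_([a-z]+)/.*$", "\\1", .data$stratum),
      genetic_group = sub("^.*prs_", "", .data$stratum)) |>
    dplyr::select("pce_group", "genetic_group", "n", "n_events",
                  hazard_ratio = "hazard_ratio", se = "std.error",
                  p = "p.value")
  class(out) <- c("stratum_table", class(out))
  out
}

#' Forest-style plot of stratum hazard ratios
#' @param object a `stratum_table` from [stratum_cox()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot stratum_table
#' @export
autoplot.stratum_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      label = paste0("PCE ", .data$pce_group, " / PRS ",
                                     .data$genetic_group),
                      hr = dplyr::coalesce(.data$hazard_ratio, 1),
                      lo = exp(log(.data$hr) - 1.96 * .data$se),
                      hi = exp(log(.data$hr) + 1.96 * .data$se))
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Analysis configuration
#'
#' Collects every pipeline setting into one serializable list; a run's
#' snapshot is written beside its outputs. All arguments have working
#' defaults, so `cvd_config()` runs the full synthetic analysis.
#'
#' @param params a [sim_params()] object describing the study to
#'   simulate (ignored when `study` is passed to [run_all()]).
#' @param qc a [qc_thresholds()] object.
#' @param logo_trait trait scored by the leave-one-group-out cross-fit
#'   instead of its supplied weight panel; `NULL` scores every trait
#'   from its panel.
#' @param logo_k,logo_p_threshold LOGO group count and weight p cutoff.
#' @param normalization `"inverse_normal"` or `"zscore"`.
#' @param cut_low,cut_high genetic-group quantile cutpoints.
#' @param cutpoint_base `"pre_exclusion"` (default: quantiles over all
#'   genotyped samples) or `"post_exclusion"`.
#' @param pce_threshold clinical high-risk threshold on 10-year risk.
#' @param age_split subgroup age split, years.
#' @param seed integer seed for the whole run.
#' @return A list of class `cvd_config`.
#' @export
cvd_config <- function(params = preset_params("table1"),
                       qc = qc_thresholds(),
                       logo_trait = "HTN", logo_k = 10L,
                       logo_p_threshold = 1,
                       normalization = c("inverse_normal", "zscore"),
                       cut_low = 0.20, cut_high = 0.80,
                       cutpoint_base = c("pre_exclusion", "post_exclusion"),
                       pce_threshold = 0.075,
                       age_split = 55,
                       seed = 1L) {
  structure(list(params = params, qc = qc, logo_trait = logo_trait,
                 logo_k = as.integer(logo_k),
                 logo_p_threshold = logo_p_threshold,
                 normalization = match.arg(normalization),
                 cut_low = cut_low, cut_high = cut_high,
                 cutpoint_base = match.arg(cutpoint_base),
                 pce_threshold = pce_threshold, age_split = age_split,
                 seed = as.integer(seed)),
            class = "cvd_config")
}

config_snapshot <- function(config) {
  drop_class <- function(x) {
    if (is.list(x)) lapply(unclass(x), drop_class) else x
  }
  yaml::as.yaml(drop_class(config))
}

#' Run the full risk-stratification analysis
#'
#' Executes every stage in order: simulate (unless a study is supplied)
#' -> genotype QC -> per-trait PRS (supplied weight panels, with one
#' trait optionally re-scored by the leakage-free LOGO cross-fit) ->
#' normalization -> logistic weighting on prevalent cases (age/sex
#' adjusted) -> weighted PRS sum and 20/60/20 genetic groups (cutpoints
#' over all genotyped samples by default, before exclusions) -> clinical
#' linear sums -> baseline exclusions -> recalibration and 10-year risk
#' -> 7.5% clinical groups -> six joint strata -> Cox, Kaplan-Meier and
#' concordance evaluation. Weighting deliberately uses prevalent cases
#' (baseline information) and those cases are then excluded from the
#' incidence analysis.
#'
#' @param config a [cvd_config()].
#' @param study optional pre-built `cvd_study` (e.g. from
#'   [generate_study()] or read from disk); otherwise simulated from
#'   `config$params` with `config$seed`.
#' @param out_dir optional directory; when given, every table, the KM
#'   curve data, the exclusion report, the config snapshot and a run log
#'   are written as CSV/YAML text files.
#' @return A list of class `cvd_report`: `scores` (per-sample score
#'   panel), `prs_weights`, `association_scan`, `genetic_group_table`,
#'   `pce_group_table`, `stratum_table`, `model_cindex`, `km_genetic`,
#'   `km_pce`, `exclusions`, `qc_reports`, `calibration`, `config`.
#' @export
run_all <- function(config = cvd_config(), study = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "cvd_config"))
  set.seed(config$seed)
  log <- character()
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  if (is.null(study)) {
    params <- config$params
    params$seed <- config$seed
    study <- generate_study(params)
  }
  cohort <- study$cohort
  say("input: %d samples, %d variants", nrow(cohort),
      ncol(study$genotypes$dosages))

  vq <- filter_variants(study$genotypes, config$qc)
  sq <- filter_samples(vq$genotypes, config$qc)
  geno <- sq$genotypes
  say("qc: %d variants and %d samples removed", vq$report$n_removed,
      sq$report$n_removed)
  cohort <- cohort[cohort$sample_id %in% rownames(geno$dosages), ]

  traits <- study$params$traits
  scores <- purrr::map(traits, function(tr) {
    if (!is.null(config$logo_trait) && tr == config$logo_trait) {
      ph <- cohort$prevalent_cvd
      logo_prs(geno, ph, k = config$logo_k,
               p_threshold = config$logo_p_threshold)$score
    } else {
      compute_prs(geno, study$weights[[tr]], trait = tr)$score
    }
  })
  names(scores) <- traits
  score_panel <- tibble::as_tibble(
    c(list(sample_id = rownames(geno$dosages)),
      purrr::map(scores, normalize_scores, method = config$normalization)))
  say("prs: %d traits scored (%s via LOGO)", length(traits),
      config$logo_trait %||% "none")

  dat <- dplyr::inner_join(cohort, score_panel, by = "sample_id")
  fit_w <- fit_prs_weights(dat, traits)
  dat <- combine_wprssum(dat, fit_w)
  scan <- prs_association_scan(dat, traits)

  base <- if (config$cutpoint_base == "pre_exclusion") dat$wprssum else NULL
  dat <- pce_linear_sum(dat)

  excl <- apply_exclusions(dat)
  analysis <- excl$data
  say("exclusions: %s", paste(excl$report$reason, excl$report$n,
                              sep = "=", collapse = ", "))

  analysis <- assign_genetic_groups(analysis, cut_low = config$cut_low,
                                    cut_high = config$cut_high, base = base)
  cal <- pce_recalibrate(analysis)
  analysis <- pce_risk(analysis, cal)
  analysis <- assign_pce_groups(analysis, threshold = config$pce_threshold)
  analysis <- combine_strata(analysis)

  genetic_tab <- genetic_group_table(analysis)
  pce_tab <- pce_group_table(analysis)
  strata_tab <- stratum_cox(analysis)
  models <- evaluate_models(analysis,
                            subgroups = default_subgroups(
                              analysis, config$age_split))
  km_g <- km_curve(analysis, group = "genetic_group")
  km_p <- km_curve(analysis, group = "pce_group")
  say("analysis set: %d samples, %d events", nrow(analysis),
      sum(analysis$event))

  report <- structure(list(
    scores = analysis, prs_weights = fit_w, association_scan = scan,
    genetic_group_table = genetic_tab, pce_group_table = pce_tab,
    stratum_table = strata_tab, model_cindex = models,
    km_genetic = km_g, km_pce = km_p,
    exclusions = excl$report,
    qc_reports = list(variants = vq$report, samples = sq$report),
    calibration = cal, config = config, log = log),
    class = "cvd_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cvd_report <- function(x, ...) {
  cat("<cvd_report>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

genetic_group_table <- function(analysis, time = "time_years",
                                event = "event") {
  fit <- fit_cox(analysis, c("genetic_group", "age", "sex"),
                 time = time, event = event)
  td <- tidy(fit)
  td <- td[grepl("^genetic_group", td$term), ]
  lev <- levels(analysis$genetic_group)
  counts <- analysis |>
    dplyr::count(.data$genetic_group, .drop = FALSE, name = "n") |>
    dplyr::left_join(
      analysis |> dplyr::filter(.data[[event]] == 1) |>
        dplyr::count(.data$genetic_group, .drop = FALSE, name = "n_events"),
      by = "genetic_group") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  # per-SD association of the continuous score, as the headline row
  sd_fit <- fit_cox(dplyr::mutate(analysis,
                                  wprs_sd = as.numeric(scale(.data$wprssum))),
                    c("wprs_sd", "age", "sex"), time = time, event = event)
  sd_row <- tidy(sd_fit)
  sd_row <- sd_row[sd_row$term == "wprs_sd", ]
  dplyr::bind_rows(
    tibble::tibble(group = "all (per SD of wPRSsum)",
                   n = nrow(analysis), n_events = sum(analysis[[event]]),
                   hazard_ratio = sd_row$hazard_ratio,
                   se = sd_row$std.error, p = sd_row$p.value),
    tibble::tibble(group = lev, n = counts$n, n_events = counts$n_events,
                   hazard_ratio = c(NA, td$hazard_ratio),
                   se = c(NA, td$std.error), p = c(NA, td$p.value)))
}

pce_group_table <- function(analysis, time = "time_years", event = "event") {
  fit <- fit_cox(analysis, c("pce_group", "age", "sex"),
                 time = time, event = event)
  td <- tidy(fit)
  td <- td[grepl("^pce_group", td$term), ]
  counts <- analysis |>
    dplyr::count(.data$pce_group, .drop = FALSE, name = "n") |>
    dplyr::left_join(
      analysis |> dplyr::filter(.data[[event]] == 1) |>
        dplyr::count(.data$pce_group, .drop = FALSE, name = "n_events"),
      by = "pce_group") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  tibble::tibble(group = levels(analysis$pce_group),
                 n = counts$n, n_events = counts$n_events,
                 hazard_ratio = c(NA, td$hazard_ratio),
                 se = c(NA, td$std.error), p = c(NA, td$p.value))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name)
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  wr(report$association_scan, "prs_association_scan")
  wr(report$genetic_group_table, "genetic_group_hr")
  wr(report$pce_group_table, "pce_group_hr")
  wr(tibble::as_tibble(report$stratum_table), "stratum_hr")
  wr(report$model_cindex, "model_cindex")
  wr(tibble::as_tibble(report$km_genetic), "km_genetic")
  wr(tibble::as_tibble(report$km_pce), "km_pce")
  wr(report$exclusions, "exclusion_report")
  wr(tidy(report$prs_weights), "prs_weights")
  wr(tibble::as_tibble(report$calibration), "pce_calibration")
  wr(report$scores[c("sample_id", "wprssum", "genetic_group", "pce_sum",
                     "pce_risk", "pce_group", "stratum")], "score_panel")
  writeLines(config_snapshot(report$config),
             file.path(out_dir, "config_snapshot.yaml"))
  writeLines(c(paste("cvdstrat", as.character(utils::packageVersion("cvdstrat"))),
               paste("seed", report$config$seed),
               report$log),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
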
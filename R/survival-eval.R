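#' Fit a Cox proportional hazards model
#'
#' Thin, validated wrapper over [survival::coxph()] with Efron tie
#' handling — the periodic visit grid guarantees heavily tied event
#' times, where Efron's approximation is the accurate standard. Constant
#' covariates are dropped with a warning; a monotone likelihood
#' (separating covariate) is an error.
#'
#' @param data tibble with follow-up and covariate columns.
#' @param covariates character vector of covariate column names; factor
#'   columns expand to indicator terms.
#' @param time,event column names of follow-up time and event flag.
#' @return An object of class `cvd_cox` (wrapping the `coxph` fit) with
#'   [tidy()] and [glance()] methods.
#' @export
fit_cox <- function(data, covariates, time = "time_years", event = "event") {
  miss <- setdiff(c(covariates, time, event), names(data))
  if (length(miss))
    abort(paste0("fit_cox: missing column(s) ", toString(miss)))
  if (sum(data[[event]]) < 1) abort("fit_cox: no events in the data")
  keep <- covariates[vapply(covariates, function(cv) {
    x <- data[[cv]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  if (length(keep) < length(covariates))
    warn(paste0("fit_cox: dropping constant covariate(s) ",
                toString(setdiff(covariates, keep))))
  if (!length(keep)) abort("fit_cox: no usable covariates")
  f <- as.formula(paste0(
    "survival::Surv(`", time, "`, `", event, "`) ~ ",
    paste(sprintf("`%s`", keep), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        abort(paste("fit_cox: monotone likelihood (a covariate separates",
                    "the risk sets)"))
      invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, covariates = keep,
                 n = fit$n, n_events = fit$nevent),
            class = "cvd_cox")
}

#' @export
print.cvd_cox <- function(x, ...) {
  cat(sprintf("<cvd_cox> %d samples, %d events\n", x$n, x$n_events))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_cox per-term hazard ratios with the SE of the log-HR
#'   and Wald p-values.
#' @param x a `cvd_cox` object.
#' @param ... unused.
#' @method tidy cvd_cox
#' @export
tidy.cvd_cox <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s),
                 hazard_ratio = exp(s[, "coef"]),
                 estimate = s[, "coef"],
                 std.error = s[, "se(coef)"],
                 p.value = s[, "Pr(>|z|)"])
}

#' @describeIn fit_cox one-row model summary (n, events, concordance,
#'   log-likelihood).
#' @method glance cvd_cox
#' @export
glance.cvd_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 concordance = unname(x$fit$concordance["concordance"]),
                 logLik = as.numeric(x$fit$loglik[2]))
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group. Censorings tied with an event time
#' remain in that time's at-risk set (the standard convention).
#'
#' @param data tibble with follow-up columns.
#' @param time,event column names.
#' @param group optional grouping column; `NULL` gives one curve.
#' @return A tibble of class `cvd_km`: `group`, `time`, `survival`,
#'   `n_risk`, `n_event`, `n_censor`, with an [ggplot2::autoplot()]
#'   method.
#' @export
km_curve <- function(data, time = "time_years", event = "event",
                     group = NULL) {
  miss <- setdiff(c(time, event, group), names(data))
  if (length(miss))
    abort(paste0("km_curve: missing column(s) ", toString(miss)))
  g <- if (is.null(group)) factor(rep("all", nrow(data))) else
    factor(data[[group]])
  if (any(table(g) == 0)) g <- droplevels(g)
  out <- purrr::map_dfr(levels(g), function(lev) {
    d <- data[g == lev, ]
    fit <- survival::survfit(survival::Surv(d[[time]], d[[event]]) ~ 1)
    tibble::tibble(group = lev, time = fit$time, survival = fit$surv,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   n_censor = fit$n.censor)
  })
  class(out) <- c("cvd_km", class(out))
  out
}

#' Plot Kaplan-Meier curves
#' @param object a `cvd_km` tibble from [km_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cvd_km
#' @export
autoplot.cvd_km <- function(object, ...) {
  start <- dplyr::distinct(object, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(start,
                         object[c("group", "time", "survival")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Years of follow-up", y = "Event-free survival",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(min(df$survival) * 0.98, 1)) +
    ggplot2::theme_minimal()
}

#' Harrell's concordance index
#'
#' Probability-style estimate over comparable pairs: pair (i, j) is
#' comparable when i has an event and `time_i < time_j`, or
#' `time_i = time_j` with j censored. A higher score for the
#' earlier-event member counts 1, a score tie 0.5. Computed via
#' [survival::concordance()] (reverse orientation: higher score = higher
#' risk).
#'
#' @param score per-sample risk score (higher = riskier).
#' @param time,event follow-up time and event flag vectors.
#' @return Concordance in \[0, 1\].
#' @export
c_index <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  cc <- survival::concordance(survival::Surv(time, event) ~ score,
                              reverse = TRUE)
  counts <- cc$count
  comparable <- counts["concordant"] + counts["discordant"] +
    counts["tied.x"]
  if (comparable == 0) abort("c_index: no comparable pairs")
  unname(cc$concordance)
}

default_model_specs <- function() {
  list(`age + sex` = c("age", "sex"),
       wprssum = "wprssum",
       `wprssum + age + sex` = c("wprssum", "age", "sex"),
       pce = "pce_risk",
       `pce + wprssum` = c("pce_risk", "wprssum"))
}

default_subgroups <- function(data, age_split = 55) {
  list(all = rep(TRUE, nrow(data)),
       men = data$sex == "male",
       women = data$sex == "female",
       `age<55` = data$age < age_split,
       `age>=55` = data$age >= age_split,
       `men age<55` = data$sex == "male" & data$age < age_split,
       `men age>=55` = data$sex == "male" & data$age >= age_split,
       `women age<55` = data$sex == "female" & data$age < age_split,
       `women age>=55` = data$sex == "female" & data$age >= age_split)
}

#' Concordance of the standard model set across subgroups
#'
#' Fits, per model specification and subgroup, a Cox model on the
#' subgroup and reports Harrell's C-index of its linear predictor. The
#' default five models are: age + sex; PRS only; PRS + age + sex; PCE
#' only; PRS + PCE (no age/sex — they are inside the PCE equation). The
#' PCE enters as the calibrated 10-year risk, which is comparable across
#' sexes (the raw linear sums are on sex-specific scales). Default
#' subgroups: all, each sex, age split at 55, and sex-by-age cells.
#' Sex-specific subgroups drop `sex` from the covariate list (it is
#' constant there).
#'
#' @param data tibble with `wprssum`, `pce_risk`, `age`, `sex` and
#'   follow-up columns.
#' @param specs named list of covariate vectors; default
#'   `default_model_specs()`.
#' @param subgroups named list of logical vectors; default
#'   `default_subgroups(data)`.
#' @param time,event follow-up column names.
#' @return A tibble `model`, `subgroup`, `n`, `n_events`, `c_index`
#'   (`NA` where a subgroup has no events).
#' @export
evaluate_models <- function(data, specs = default_model_specs(),
                            subgroups = default_subgroups(data),
                            time = "time_years", event = "event") {
  purrr::map_dfr(names(specs), function(mn) {
    purrr::map_dfr(names(subgroups), function(sn) {
      d <- data[subgroups[[sn]], ]
      ne <- sum(d[[event]])
      if (nrow(d) < 2 || ne == 0)
        return(tibble::tibble(model = mn, subgroup = sn, n = nrow(d),
                              n_events = ne, c_index = NA_real_))
      covs <- specs[[mn]]
      covs <- covs[vapply(covs, function(cv)
        length(unique(d[[cv]])) > 1, logical(1))]
      if (!length(covs))
        return(tibble::tibble(model = mn, subgroup = sn, n = nrow(d),
                              n_events = ne, c_index = NA_real_))
      ci <- tryCatch({
        fit <- fit_cox(d, covs, time = time, event = event)
        lp <- predict(fit$fit, type = "lp")
        c_index(lp, d[[time]], d[[event]])
      }, error = function(e) NA_real_)   # degenerate subgroup -> missing cell
      tibble::tibble(model = mn, subgroup = sn, n = nrow(d), n_events = ne,
                     c_index = ci)
    })
  })
}
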
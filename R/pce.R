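#' Sex-specific pooled-cohort-equation coefficients
#'
#' The shipped preset is the recalibrated East-Asian coefficient set on
#' natural-log-transformed covariates. Men's sum carries an
#' age-by-smoking interaction; women's carries age-by-blood-pressure
#' interactions for both the treated and untreated pathways. Exactly one
#' blood-pressure pathway is active per person: if treated,
#' `TRSBP = SBP` and `UNSBP = 1` (its log terms vanish), else the
#' reverse.
#'
#' @return A list of class `pce_coefficients` with elements `male` and
#'   `female`, each a named coefficient vector.
#' @export
pce_coefficients <- function() {
  structure(list(
    male = c(ln_age = 4.950, ln_tc = 0.943, ln_hdl = -0.693,
             ln_trsbp = 1.101, ln_unsbp = 1.002,
             cusmok = 5.485, ln_age_cusmok = -1.287, dm = 0.558),
    female = c(ln_age = 36.699, ln_tc = 0.625, ln_hdl = -0.449,
               ln_trsbp = 29.947, ln_age_ln_trsbp = -7.010,
               ln_unsbp = 29.255, ln_age_ln_unsbp = -6.847,
               cusmok = 0.497, dm = 0.962)),
    class = "pce_coefficients")
}

#' Evaluate the pooled-cohort-equation linear sum
#'
#' Computes the sex-specific linear sum on the natural-log scale for each
#' row. Required columns: `sex`, `age`, `tc`, `hdl`, `sbp`, `bp_treated`,
#' `smoker`, `diabetes` (the last three 0/1).
#'
#' @param data clinical tibble (see above).
#' @param coef a [pce_coefficients()] object.
#' @return `data` with a new `pce_sum` column.
#' @export
pce_linear_sum <- function(data, coef = pce_coefficients()) {
  stopifnot(inherits(coef, "pce_coefficients"))
  need <- c("sex", "age", "tc", "hdl", "sbp", "bp_treated", "smoker",
            "diabetes")
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste0("pce_linear_sum: missing column(s) ", toString(miss)))
  with_cols <- data[need]
  ok <- complete.cases(with_cols)
  if (any(with_cols$tc[ok] <= 0 | with_cols$hdl[ok] <= 0 |
          with_cols$sbp[ok] <= 0))
    abort("pce_linear_sum: TC, HDL and SBP must be positive")
  ln_age <- log(data$age)
  ln_tc <- log(data$tc)
  ln_hdl <- log(data$hdl)
  treated <- data$bp_treated == 1
  ln_trsbp <- ifelse(treated, log(data$sbp), 0)   # log(1) = 0 when inactive
  ln_unsbp <- ifelse(treated, 0, log(data$sbp))
  smok <- as.numeric(data$smoker)
  dm <- as.numeric(data$diabetes)
  m <- coef$male
  f <- coef$female
  sum_m <- m["ln_age"] * ln_age + m["ln_tc"] * ln_tc +
    m["ln_hdl"] * ln_hdl + m["ln_trsbp"] * ln_trsbp +
    m["ln_unsbp"] * ln_unsbp + m["cusmok"] * smok +
    m["ln_age_cusmok"] * ln_age * smok + m["dm"] * dm
  sum_f <- f["ln_age"] * ln_age + f["ln_tc"] * ln_tc +
    f["ln_hdl"] * ln_hdl + f["ln_trsbp"] * ln_trsbp +
    f["ln_age_ln_trsbp"] * ln_age * ln_trsbp +
    f["ln_unsbp"] * ln_unsbp + f["ln_age_ln_unsbp"] * ln_age * ln_unsbp +
    f["cusmok"] * smok + f["dm"] * dm
  dplyr::mutate(data,
                pce_sum = as.numeric(ifelse(data$sex == "male", sum_m, sum_f)))
}

#' Recalibrate the risk equation on a cohort
#'
#' Estimates, per sex, the cohort mean linear sum and the 10-year
#' baseline survival `S0(10)` from the Kaplan-Meier estimator of the
#' incident-event process. These two quantities adapt the fixed
#' coefficient set to a cohort with its own risk-factor distribution and
#' event rate.
#'
#' @param data tibble with `pce_sum`, `sex` and follow-up columns.
#' @param time,event column names of follow-up time (years) and the
#'   event flag.
#' @param horizon risk horizon in years (default 10).
#' @return A tibble of class `pce_calibration`: `sex`, `mean_sum`,
#'   `s0`, `horizon`.
#' @export
pce_recalibrate <- function(data, time = "time_years", event = "event",
                            horizon = 10) {
  miss <- setdiff(c("pce_sum", "sex", time, event), names(data))
  if (length(miss))
    abort(paste0("pce_recalibrate: missing column(s) ", toString(miss)))
  out <- purrr::map_dfr(c("male", "female"), function(s) {
    d <- data[data$sex == s, ]
    if (nrow(d) < 2)
      abort(paste0("pce_recalibrate: need >= 2 samples of sex ", s))
    if (max(d[[time]]) < horizon)
      abort(paste0("pce_recalibrate: no follow-up reaching ", horizon,
                   " years for sex ", s))
    km <- survival::survfit(
      survival::Surv(d[[time]], d[[event]]) ~ 1)
    s0 <- summary(km, times = horizon, extend = TRUE)$surv
    tibble::tibble(sex = s, mean_sum = mean(d$pce_sum), s0 = s0,
                   horizon = horizon)
  })
  class(out) <- c("pce_calibration", class(out))
  out
}

#' Convert linear sums to 10-year risk
#'
#' `risk = 1 - s0 ^ exp(sum - mean_sum)`, using the calibration row of
#' the person's sex. Strictly increasing in the sum; lies in \[0, 1).
#'
#' @param data tibble with `pce_sum` and `sex`.
#' @param calibration a [pce_recalibrate()] result (or a tibble with
#'   columns `sex`, `mean_sum`, `s0`).
#' @return `data` with a new `pce_risk` column.
#' @export
pce_risk <- function(data, calibration) {
  miss <- setdiff(c("pce_sum", "sex"), names(data))
  if (length(miss))
    abort(paste0("pce_risk: missing column(s) ", toString(miss)))
  if (any(calibration$s0 <= 0 | calibration$s0 > 1))
    abort("pce_risk: baseline survival must lie in (0, 1]")
  i <- match(data$sex, calibration$sex)
  if (anyNA(i))
    abort("pce_risk: calibration missing for some sex value")
  s0 <- calibration$s0[i]
  mean_sum <- calibration$mean_sum[i]
  dplyr::mutate(data,
                pce_risk = 1 - s0^exp(data$pce_sum - mean_sum))
}

#' Assign low / high clinical risk groups
#'
#' `high` iff `risk >= threshold` (boundary inclusive on high).
#'
#' @param data tibble with the risk column.
#' @param risk risk column name (default `"pce_risk"`).
#' @param threshold risk threshold (default 0.075, the 7.5% convention).
#' @return `data` with a `pce_group` factor (`low`, `high`).
#' @export
assign_pce_groups <- function(data, risk = "pce_risk", threshold = 0.075) {
  if (!risk %in% names(data))
    abort(paste0("assign_pce_groups: missing column '", risk, "'"))
  r <- data[[risk]]
  if (any(r < 0 | r > 1, na.rm = TRUE))
    abort("assign_pce_groups: risks must lie in [0, 1]")
  dplyr::mutate(data, pce_group = factor(
    ifelse(r >= threshold, "high", "low"), levels = c("low", "high")))
}
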
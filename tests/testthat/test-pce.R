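unit_record <- function(sex) {
  tibble::tibble(sex = sex, age = 1, tc = 1, hdl = 1, sbp = 1,
                 bp_treated = 0, smoker = 0, diabetes = 0)
}

male_record <- function(age = 55, tc = 192, hdl = 45, sbp = 117,
                        bp_treated = 0, smoker = 1, diabetes = 0) {
  tibble::tibble(sex = "male", age = age, tc = tc, hdl = hdl, sbp = sbp,
                 bp_treated = bp_treated, smoker = smoker,
                 diabetes = diabetes)
}

test_that("the shipped coefficient preset carries the exact printed values", {
  co <- pce_coefficients()
  expect_identical(unname(co$male),
                   c(4.950, 0.943, -0.693, 1.101, 1.002, 5.485, -1.287,
                     0.558))
  expect_identical(unname(co$female),
                   c(36.699, 0.625, -0.449, 29.947, -7.010, 29.255, -6.847,
                     0.497, 0.962))
})

test_that("the unit record zeroes every log term for both sexes", {
  expect_equal(pce_linear_sum(unit_record("male"))$pce_sum, 0)
  expect_equal(pce_linear_sum(unit_record("female"))$pce_sum, 0)
})

test_that("the male sum matches a term-by-term hand calculation", {
  r <- male_record()
  # independent arithmetic, written out literally
  expected <- 4.950 * log(55) + 0.943 * log(192) - 0.693 * log(45) +
    1.101 * log(1) + 1.002 * log(117) + 5.485 * 1 -
    1.287 * log(55) * 1 + 0.558 * 0
  expect_equal(pce_linear_sum(r)$pce_sum, expected, tolerance = 1e-12)
  # treated variant: the blood-pressure term switches pathway
  rt <- male_record(bp_treated = 1)
  expected_t <- expected - 1.002 * log(117) + 1.101 * log(117)
  expect_equal(pce_linear_sum(rt)$pce_sum, expected_t, tolerance = 1e-12)
})

test_that("the female sum matches a term-by-term hand calculation", {
  r <- tibble::tibble(sex = "female", age = 52, tc = 191, hdl = 46,
                      sbp = 117, bp_treated = 1, smoker = 0, diabetes = 1)
  expected <- 36.699 * log(52) + 0.625 * log(191) - 0.449 * log(46) +
    29.947 * log(117) - 7.010 * log(52) * log(117) +
    29.255 * log(1) - 6.847 * log(52) * log(1) + 0.497 * 0 + 0.962 * 1
  expect_equal(pce_linear_sum(r)$pce_sum, expected, tolerance = 1e-12)
})

test_that("male smoking shifts the sum by its age-interacted coefficient", {
  for (age in c(42, 55, 68)) {
    s1 <- pce_linear_sum(male_record(age = age, smoker = 1))$pce_sum
    s0 <- pce_linear_sum(male_record(age = age, smoker = 0))$pce_sum
    expect_equal(s1 - s0, 5.485 - 1.287 * log(age), tolerance = 1e-12)
  }
})

test_that("the sum rises with cholesterol and falls with HDL for both sexes", {
  for (sex in c("male", "female")) {
    base <- tibble::tibble(sex = sex, age = 55, tc = 180, hdl = 45,
                           sbp = 120, bp_treated = 0, smoker = 0,
                           diabetes = 0)
    up_tc <- dplyr::mutate(base, tc = 220)
    dn_hdl <- dplyr::mutate(base, hdl = 60)
    expect_gt(pce_linear_sum(up_tc)$pce_sum, pce_linear_sum(base)$pce_sum)
    expect_lt(pce_linear_sum(dn_hdl)$pce_sum, pce_linear_sum(base)$pce_sum)
  }
  expect_error(pce_linear_sum(dplyr::mutate(unit_record("male"), tc = -1)),
               "positive")
})

test_that("recalibration reproduces hand Kaplan-Meier baselines", {
  toy <- tibble::tibble(
    sex = rep(c("male", "female"), each = 5),
    pce_sum = rep(c(3, 3, 3, 3, 3), 2),
    time_years = rep(c(2, 4, 6, 8, 12), 2),
    event = rep(c(1, 0, 1, 0, 0), 2))
  cal <- pce_recalibrate(toy)
  # product-limit by hand: events at t=2 (5 at risk) and t=6 (3 at risk)
  expect_equal(cal$s0, rep((4 / 5) * (2 / 3), 2))
  expect_equal(cal$s0, rep(oracle_km(toy$time_years[1:5],
                                     toy$event[1:5], 10), 2))
  expect_equal(cal$mean_sum, c(3, 3))
  # no events before the horizon: baseline survival 1
  none <- dplyr::mutate(toy, event = 0)
  expect_equal(pce_recalibrate(none)$s0, c(1, 1))
  short <- dplyr::mutate(toy, time_years = time_years / 2)
  expect_error(pce_recalibrate(short), "reaching")
})

test_that("risk conversion follows its closed form and stays monotone", {
  cal <- tibble::tibble(sex = c("male", "female"),
                        mean_sum = c(10, 100), s0 = c(0.95, 0.9),
                        horizon = 10)
  d <- tibble::tibble(sex = "male", pce_sum = 10.5)
  expect_equal(pce_risk(d, cal)$pce_risk, 1 - 0.95^exp(0.5),
               tolerance = 1e-12)
  at_mean <- tibble::tibble(sex = c("male", "female"),
                            pce_sum = c(10, 100))
  expect_equal(pce_risk(at_mean, cal)$pce_risk,
               c(1 - 0.95, 1 - 0.9))
  cal1 <- dplyr::mutate(cal, s0 = 1)
  expect_equal(pce_risk(at_mean, cal1)$pce_risk, c(0, 0))
  sums <- tibble::tibble(sex = "male", pce_sum = seq(8, 12, by = 0.5))
  risks <- pce_risk(sums, cal)$pce_risk
  expect_true(all(diff(risks) > 0))
  expect_true(all(risks >= 0 & risks < 1))
  bad <- dplyr::mutate(cal, s0 = c(0, 0.5))
  expect_error(pce_risk(at_mean, bad), "survival")
})

test_that("the 7.5% threshold is inclusive on the high side", {
  d <- tibble::tibble(pce_risk = c(0.0749, 0.0750, 0, 1))
  g <- assign_pce_groups(d)
  expect_identical(as.character(g$pce_group),
                   c("low", "high", "low", "high"))
  zero <- assign_pce_groups(tibble::tibble(pce_risk = rep(0, 5)))
  expect_true(all(zero$pce_group == "low"))
  set.seed(71)
  u <- assign_pce_groups(tibble::tibble(pce_risk = runif(20000)))
  se <- sqrt(0.925 * 0.075 / 20000)
  expect_lt(abs(mean(u$pce_group == "high") - 0.925), 3 * se)
})

test_that("mean predicted risk matches the 10-year event mass on a cohort", {
  # first-order identity, valid in the small-risk regime
  st <- small_study(n = 3000, m = 30, seed = 72, baseline_hazard = 0.003)
  co <- pce_linear_sum(st$cohort[st$cohort$prevalent_cvd == 0, ])
  cal <- pce_recalibrate(co)
  co <- pce_risk(co, cal)
  km_all <- oracle_km(co$time_years, co$event, 10)
  expect_lt(abs(mean(co$pce_risk) - (1 - km_all)), 0.01)
})
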
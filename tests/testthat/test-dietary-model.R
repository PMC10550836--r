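test_that("counterfactual rules: cap for sodium/sugars, floor for whole grains", {
  # offered-limit cap net of 10% plate waste
  expect_equal(counterfactual_intake(900, 510, "sodium", waste_fraction = 0.1), 459)
  # meals already under the limit are never raised to it
  expect_equal(counterfactual_intake(400, 510, "sodium", waste_fraction = 0.1), 400)
  # partial compliance is the convex combination
  expect_equal(
    counterfactual_intake(900, 510, "sodium", waste_fraction = 0.1,
                          noncompliance = 0.3, scenario = "partial"),
    0.3 * 900 + 0.7 * 459)
  # whole grain floor: half the grain mass, net of waste
  expect_equal(
    counterfactual_intake(5, NA, "whole_grain", waste_fraction = 0.2,
                          total_grain = 40, whole_grain_rich_fraction = 0.5),
    0.5 * 40 * 0.8)
  # already whole-grain-rich meals are untouched
  expect_equal(
    counterfactual_intake(30, NA, "whole_grain", total_grain = 40), 30)
  expect_error(counterfactual_intake(5, NA, "whole_grain"),
               class = "smc_contract_error")
})

test_that("record-level counterfactual honours the grade-band contract", {
  rec <- collapse_child_days(single_child_records())
  std_lunch <- STANDARDS[STANDARDS$meal == "lunch" & STANDARDS$grade_band == "K5", ]
  out <- counterfactual_meal_intake(rec, std_lunch, COMPLIANCE, "full")
  expect_equal(nrow(out), 3)
  na_row <- out[out$factor == "sodium", ]
  w <- COMPLIANCE$waste_fraction[COMPLIANCE$factor == "sodium" &
                                   COMPLIANCE$meal == "lunch" &
                                   COMPLIANCE$grade_band == "K5"]
  expect_equal(na_row$counterfactual, min(900, 510 * (1 - w)))
  std_hs <- STANDARDS[STANDARDS$meal == "lunch" & STANDARDS$grade_band == "912", ]
  expect_error(counterfactual_meal_intake(rec, std_hs, COMPLIANCE, "full"),
               class = "smc_contract_error")
})

test_that("single-child habitual change matches hand arithmetic", {
  # lunch-only participation 180/365, sodium 900 -> 459 under 10% waste
  pars <- PARS
  pars$compliance$waste_fraction$sodium <- 0.10
  comp <- build_compliance_model(pars)
  recs <- single_child_records(lunch_participation = 180 / 365,
                               lunch_sodium = 900)
  hc <- habitual_change(recs, STANDARDS, comp, "full")
  d <- hc$delta_mean[hc$factor == "sodium"]
  expect_equal(d, (180 / 365) * (459 - 900))  # about -217.5 mg/d
  expect_equal(hc$se_delta[hc$factor == "sodium"], 0)
})

test_that("person-level change is linear in the participation fraction", {
  pars <- PARS
  pars$compliance$waste_fraction$sodium <- 0.10
  comp <- build_compliance_model(pars)
  d1 <- habitual_change(single_child_records(lunch_participation = 0.2),
                        STANDARDS, comp, "full")
  d2 <- habitual_change(single_child_records(lunch_participation = 0.4),
                        STANDARDS, comp, "full")
  expect_equal(2 * d1$delta_mean[d1$factor == "sodium"],
               d2$delta_mean[d2$factor == "sodium"])
})

test_that("no-harm conservatism holds for every record", {
  kids <- KIDS
  ch <- collapse_child_days(kids)
  for (meal in c("breakfast", "lunch")) {
    prefix <- if (meal == "breakfast") "school_breakfast_" else "school_lunch_"
    lims <- STANDARDS[STANDARDS$meal == meal, ]
    lim_na <- stats::setNames(lims$sodium_max_mg, lims$grade_band)[ch$grade_band]
    cf <- counterfactual_intake(ch[[paste0(prefix, "sodium_mg")]], lim_na,
                                "sodium", waste_fraction = 0.12)
    expect_true(all(cf <= ch[[paste0(prefix, "sodium_mg")]] + 1e-12))
    cfw <- counterfactual_intake(ch[[paste0(prefix, "whole_grain_g")]], NA,
                                 "whole_grain", waste_fraction = 0.25,
                                 total_grain = ch[[paste0(prefix, "total_grain_g")]])
    expect_true(all(cfw >= ch[[paste0(prefix, "whole_grain_g")]] - 1e-12))
  }
})

test_that("partial-compliance changes are attenuated, equal only when p = 0", {
  hc_full <- habitual_change(KIDS, STANDARDS, COMPLIANCE, "full")
  hc_part <- habitual_change(KIDS, STANDARDS, COMPLIANCE, "partial")
  m <- dplyr::inner_join(hc_full, hc_part, by = c("grade_band", "factor"),
                         suffix = c("_f", "_p"))
  expect_true(all(abs(m$delta_mean_p) <= abs(m$delta_mean_f) + 1e-12))
  expect_true(all(abs(m$delta_mean_p) < abs(m$delta_mean_f)))  # p > 0 here
  comp0 <- COMPLIANCE
  comp0$noncompliance <- 0
  hc_p0 <- habitual_change(KIDS, STANDARDS, comp0, "partial")
  expect_equal(hc_p0$delta_mean, hc_full$delta_mean)
})

test_that("magnitude of sodium/sugar change is nonincreasing in plate waste", {
  deltas <- sapply(c(0, 0.1, 0.2, 0.3), function(w) {
    pars <- PARS
    pars$compliance$waste_fraction$sodium <- w
    hc <- habitual_change(KIDS, STANDARDS, build_compliance_model(pars), "full")
    hc$delta_mean[hc$factor == "sodium" & hc$grade_band == "K5"]
  })
  expect_true(all(diff(abs(deltas)) >= 0))  # tighter effective limit, larger drop
})

test_that("population under every limit yields zero sugar/sodium change", {
  recs <- single_child_records(lunch_sodium = 100, lunch_sugar = 2)
  hc <- habitual_change(recs, STANDARDS, COMPLIANCE, "full")
  expect_equal(hc$delta_mean[hc$factor == "sodium"], 0)
  expect_equal(hc$delta_mean[hc$factor == "added_sugar"], 0)
})

test_that("percent change reproduces reported rounding and guards baseline", {
  expect_equal(percent_change(-2.72, 69.5), -3.9)
  expect_equal(percent_change(7.29, 27.3), 26.7)
  expect_equal(percent_change(0, 5), 0)
  expect_error(percent_change(1, 0), class = "smc_parameter_error")
})

test_that("usual-intake estimator: single-day means, degenerate variances", {
  recs <- single_child_records()
  recs2 <- dplyr::bind_rows(recs, dplyr::mutate(recs, person_id = "C2",
                                                survey_weight = 3))
  # single-day input: usual mean is the weighted mean, with a warning that
  # no within-person variance can be estimated
  expect_warning(ui <- estimate_usual_intake(recs2, "sodium"),
                 "no repeat recall days")
  manual <- collapse_child_days(recs2)
  expect_equal(ui$mean,
               weighted_mean_se(habitual_daily_intake(manual, "sodium"),
                                manual$survey_weight)$mean)
  expect_equal(ui$var_within, 0)
  # all-equal intakes give zero variance components
  eq <- dplyr::bind_rows(recs2, dplyr::mutate(recs2, day = 2L))
  ui_eq <- suppressWarnings(estimate_usual_intake(eq, "sodium"))
  expect_equal(ui_eq$var_within, 0)
  expect_equal(ui_eq$var_between, 0)
  # a stratum with a single record is an estimation error naming it
  expect_error(estimate_usual_intake(recs, "sodium"),
               class = "smc_estimation_error", regexp = "K5")
})

test_that("usual-intake estimator recovers a known variance split", {
  # two recall days per person with known log-scale components
  set.seed(99)
  n <- 5000
  s2b <- 4; s2w <- 1
  b <- rnorm(n, 0, sqrt(s2b))
  recs <- purrr::map_dfr(1:2, function(d) {
    r <- single_child_records()
    r[rep(1, n), ] |>
      dplyr::mutate(person_id = sprintf("P%05d", 1:n), day = d,
                    other_sodium_mg = exp(5 + b + rnorm(n, 0, sqrt(s2w))),
                    lunch_participation = 0, breakfast_participation = 0,
                    school_lunch_sodium_mg = 0)
  })
  ui <- estimate_usual_intake(recs, "sodium")
  expect_lt(abs(ui$var_within / s2w - 1), 0.15)
  expect_lt(abs(ui$var_between / s2b - 1), 0.15)
  # method-of-moments oracle computed independently
  y <- cbind(log(recs$other_sodium_mg[recs$day == 1]),
             log(recs$other_sodium_mg[recs$day == 2]))
  vw_oracle <- mean(apply(y, 1, var))
  vb_oracle <- var(rowMeans(y)) - vw_oracle / 2
  expect_equal(ui$var_within, vw_oracle, tolerance = 1e-8)
  expect_equal(ui$var_between, vb_oracle, tolerance = 1e-8)
})
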
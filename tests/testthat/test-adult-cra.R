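test_that("persistence scales the population-weighted childhood change", {
  ch <- tibble::tibble(grade_band = "K5", factor = "sodium",
                       delta_mean = -165, se_delta = 0)
  expect_equal(unname(persist_change(ch, 0.35)["sodium"]), -57.75)
  expect_equal(unname(persist_change(ch, 0)["sodium"]), 0)
  expect_equal(persist_change(ch, 0.50)["sodium"],
               2 * persist_change(ch, 0.25)["sodium"])
  # grade weighting
  ch2 <- tibble::tibble(grade_band = c("K5", "912"), factor = "sodium",
                        delta_mean = c(-100, -200), se_delta = 0)
  w <- c(K5 = 0.75, `912` = 0.25)
  expect_equal(unname(persist_change(ch2, 1, w)["sodium"]), -125)
  expect_error(persist_change(ch2, 1.5), class = "smc_parameter_error")
  expect_error(persist_change(ch2[0, ], 0.35), class = "smc_contract_error")
})

test_that("log-linear relative risks follow the closed form", {
  expect_equal(relative_risk_for_change(1.2, -50, per = 50), 1 / 1.2)
  expect_equal(relative_risk_for_change(1.3, 0, per = 50), 1)
  expect_equal(relative_risk_for_change(1.1, 2, per = 1), 1.21)
  expect_error(relative_risk_for_change(-1, 1), class = "smc_parameter_error")
})

test_that("mediated relative risks chain units and blend modifier strata", {
  # delta_diet -> delta_BMI = -0.5 kg/m2 against RR 1.25 per 5 kg/m2
  expect_equal(mediated_relative_risk(0.01, 1.25, -50, per = 5),
               exp(log(1.25) * (-0.1)))
  expect_equal(mediated_relative_risk(0.01, 1.25, 0, per = 5), 1)
  # prevalence-weighted blend equals direct stratum enumeration
  mods <- tibble::tibble(prevalence = c(0.55, 0.45),
                         effect_mult = c(0.6, 1.49))
  blended <- mediated_relative_risk(2.0, 1.8, -0.5, per = 10, modifiers = mods)
  manual <- sum(mods$prevalence *
                  exp(log(1.8) / 10 * (-0.5) * 2.0 * mods$effect_mult))
  expect_equal(blended, manual)
  expect_error(
    mediated_relative_risk(1, 1.2, 1, per = 5,
                           modifiers = tibble::tibble(prevalence = c(0.5, 0.4))),
    class = "smc_contract_error")
})

test_that("uniform-shift PIF equals the closed form and keeps its sign convention", {
  expect_equal(pif_for_factor(1), 0)
  expect_equal(pif_for_factor(exp(log(1.2) * -1)), 1 - 1 / 1.2)
  expect_equal(pif_for_factor(1.05), -0.05)
  expect_error(pif_for_factor(-0.1), class = "smc_parameter_error")
})

test_that("joint multiplicative PIF is order-invariant with known identities", {
  expect_equal(joint_pif(c(0, 0, 0)), 0)
  expect_equal(joint_pif(c(0.1, 0.2)), 0.28)
  expect_equal(joint_pif(0.37), 0.37)
  expect_equal(joint_pif(c(0.3, -0.1, 0.05)), joint_pif(c(0.05, 0.3, -0.1)))
  expect_error(joint_pif(c(0.2, 1.2)), class = "smc_contract_error")
  # bounds for nonnegative PIFs
  ps <- c(0.1, 0.25, 0.05)
  expect_lte(joint_pif(ps), sum(ps))
  expect_gte(joint_pif(ps), max(ps))
})

test_that("burden attribution matches a hand-computed aggregation", {
  rates <- tibble::tibble(
    age_band = c("65-74", "75+"), sex = "female", race_eth = "NH-White",
    population_count = 1e6, disease = "CHD",
    deaths_per_year = c(500, 300))
  pifs <- tibble::tibble(
    disease = "CHD", age_band = c("65-74", "75+"), race_eth = "NH-White",
    factor = "sodium", rr_total = 1, pif = c(0.1, 0.2),
    pif_joint = c(0.1, 0.2))
  dalys <- tibble::tibble(age_band = c("65-74", "75+"), sex = "female",
                          disease = "CHD", dalys_per_year = c(1000, 600))
  costs <- tibble::tibble(disease_group = "CVD",
                          direct_cost_busd2019 = 10,
                          indirect_cost_busd2019 = 5)
  b <- attribute_burden(pifs, rates, dalys, costs)
  expect_equal(b$total$deaths_prevented, 0.1 * 500 + 0.2 * 300)  # 110
  expect_equal(b$by_group$cost_pif, 110 / 800)
  expect_equal(b$total$direct_savings_busd, 110 / 800 * 10)
  expect_equal(b$total$indirect_savings_busd, 110 / 800 * 5)
  expect_equal(b$total$total_savings_busd, 110 / 800 * 15)
  expect_equal(b$total$dalys_prevented, 0.1 * 1000 + 0.2 * 600)
  # all-zero PIFs give zero burden
  b0 <- attribute_burden(dplyr::mutate(pifs, pif = 0, pif_joint = 0),
                         rates, dalys, costs)
  expect_equal(b0$total$deaths_prevented, 0)
  expect_equal(b0$total$total_savings_busd, 0)
})

test_that("deaths prevented never exceed total deaths when PIFs are below 1", {
  adult <- generate_adult_inputs(seed = 6, pars = PARS)
  deltas <- c(added_sugar = -1, sodium = -60, whole_grain = 2)
  pifs <- adult_pifs(deltas, PARS)
  expect_true(all(pifs$pif <= 1))
  b <- attribute_burden(pifs, adult$rates, adult$dalys, adult$costs)
  expect_lte(b$total$deaths_prevented, sum(adult$rates$deaths_per_year))
})

test_that("null dietary change gives unit RRs and zero PIFs end to end", {
  deltas <- c(added_sugar = 0, sodium = 0, whole_grain = 0)
  pifs <- adult_pifs(deltas, PARS)
  expect_true(all(abs(pifs$pif) < 1e-12))
  expect_true(all(abs(pifs$pif_joint) < 1e-12))
})

test_that("the precompiled engine reproduces the reference PIF route", {
  deltas <- c(added_sugar = -0.95, sodium = -57.75, whole_grain = 2.1)
  rr_tab <- expand_rr_library(PARS)
  set.seed(31)
  rr_z <- stats::setNames(rnorm(length(unique(rr_tab$rr_key))),
                          unique(rr_tab$rr_key))
  eff <- list(added_sugar_bmi = 0.012, whole_grain_bmi = -0.009,
              sodium_sbp = 2.4)
  ref <- adult_pifs(deltas, PARS, rr_tab, rr_z = rr_z, effect_draw = eff)
  eng <- schoolmealcra:::build_pif_engine(PARS)(deltas, rr_z = rr_z,
                                                effect_draw = eff)
  joined <- dplyr::distinct(ref, disease, age_band, race_eth, pif_joint) |>
    dplyr::left_join(dplyr::mutate(eng$cells, pj = eng$pif_joint),
                     by = c("disease", "age_band", "race_eth"))
  expect_equal(joined$pif_joint, joined$pj, tolerance = 1e-12)
  # per-factor PIFs agree too
  for (fi in seq_along(c("added_sugar", "sodium", "whole_grain"))) {
    f <- c("added_sugar", "sodium", "whole_grain")[fi]
    jf <- ref[ref$factor == f, ] |>
      dplyr::left_join(dplyr::mutate(eng$cells, pf = eng$pif_factor[, fi]),
                       by = c("disease", "age_band", "race_eth"))
    expect_equal(jf$pif, jf$pf, tolerance = 1e-12)
  }
  # attribution engine vs reference attribution
  adult <- generate_adult_inputs(seed = 6, pars = PARS)
  att <- schoolmealcra:::build_attribution_engine(eng$cells, adult)
  fast <- att(eng$pif_joint)
  slow <- attribute_burden(ref, adult$rates, adult$dalys, adult$costs)
  expect_equal(sum(fast$deaths_prevented), slow$total$deaths_prevented)
  expect_equal(sum(fast$dalys_prevented), slow$total$dalys_prevented)
  expect_equal(sum(fast$total), slow$total$total_savings_busd)
})
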
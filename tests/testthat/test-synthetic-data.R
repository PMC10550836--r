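test_that("child generator output satisfies its invariants", {
  kids <- KIDS
  intake_cols <- grep("_(g|mg)$", names(kids), value = TRUE)
  expect_true(all(as.matrix(kids[intake_cols]) >= 0))
  expect_true(all(kids$breakfast_participation >= 0 &
                    kids$breakfast_participation <= 1))
  expect_true(all(kids$lunch_participation >= 0 & kids$lunch_participation <= 1))
  expect_true(all(kids$survey_weight > 0))
  # grade band consistent with age
  expect_true(all(kids$grade_band[kids$age_y <= 10] == "K5"))
  expect_true(all(kids$grade_band[kids$age_y >= 14] == "912"))
  expect_true(all(kids$grade_band[kids$age_y %in% 11:13] == "68"))
  # never-participants have zero school intake
  z <- kids[kids$lunch_participation == 0, ]
  if (nrow(z)) expect_true(all(z$school_lunch_sodium_mg == 0))
  # whole grain never exceeds total grain mass
  expect_true(all(kids$school_lunch_whole_grain_g <=
                    kids$school_lunch_total_grain_g + 1e-12))
})

test_that("generators are deterministic under a fixed seed", {
  a <- generate_child_population(500, seed = 7, pars = PARS)
  b <- generate_child_population(500, seed = 7, pars = PARS)
  expect_identical(a, b)
  c2 <- generate_child_population(500, seed = 8, pars = PARS)
  expect_false(identical(a, c2))
  x <- generate_adult_inputs(seed = 5, pars = PARS)
  y <- generate_adult_inputs(seed = 5, pars = PARS)
  expect_identical(x, y)
})

test_that("degenerate generator requests are rejected", {
  expect_error(generate_child_population(0, seed = 1, pars = PARS),
               class = "smc_parameter_error")
  bad <- PARS
  bad$generator$child$log_sd_between <- -1
  expect_error(generate_child_population(10, seed = 1, pars = bad),
               class = "smc_parameter_error")
})

test_that("grade-level habitual means converge to the configured targets", {
  cfg <- PARS$generator$child
  # analytic expectation of the habitual mean implied by the configuration:
  # E[habitual] = other + sum over meals of E[participation] * meal mean,
  # with whole grain as the mean grain share times grain mass
  frac <- function(meal, g) {
    unlist(cfg$participation[[meal]])[[g]] * cfg$school_year_days / 365
  }
  analytic <- function(f, g) {
    if (f == "whole_grain") {
      cfg$grain_share$other * cfg$meal_mean$total_grain$other[[g]] +
        cfg$grain_share$school *
        (frac("breakfast", g) * cfg$meal_mean$total_grain$breakfast[[g]] +
           frac("lunch", g) * cfg$meal_mean$total_grain$lunch[[g]])
    } else {
      cfg$meal_mean[[f]]$other[[g]] +
        frac("breakfast", g) * cfg$meal_mean[[f]]$breakfast[[g]] +
        frac("lunch", g) * cfg$meal_mean[[f]]$lunch[[g]]
    }
  }
  kids <- generate_child_population(20000, seed = 12, pars = PARS)
  ch <- collapse_child_days(kids)
  for (f in c("added_sugar", "sodium", "whole_grain")) {
    v <- habitual_daily_intake(ch, f)
    for (g in c("K5", "68", "912")) {
      tgt <- unlist(PARS$generator$child$habitual_targets[[f]])[[g]]
      # calibration: the configured generator means imply the target
      expect_lt(abs(analytic(f, g) / tgt - 1), 0.01)
      # simulation: the realised mean is consistent with the target
      # within Monte Carlo error
      wm <- weighted_mean_se(v[ch$grade_band == g],
                             ch$survey_weight[ch$grade_band == g])
      expect_lt(abs(wm$mean - tgt), 4 * wm$se)
    }
  }
})

test_that("adult inputs cover the full 48-stratum crossing with valid tables", {
  adult <- generate_adult_inputs(seed = 2, pars = PARS)
  strata <- dplyr::distinct(adult$intakes, age_band, sex, race_eth)
  expect_equal(nrow(strata), 48)
  expect_true(all(adult$rates$deaths_per_year >= 0))
  expect_true(all(adult$dalys$dalys_per_year >= 0))
  expect_false("race_eth" %in% names(adult$dalys))
  expect_true(all(adult$intakes$mean_intake >= 0))
  # sex-specific cancers carry no deaths in the other sex
  breast_m <- adult$rates[adult$rates$disease == "cancer_breast" &
                            adult$rates$sex == "male", ]
  expect_true(all(breast_m$deaths_per_year == 0))
})

test_that("default cost table reproduces the national totals", {
  adult <- generate_adult_inputs(seed = 1, pars = PARS)
  costs <- adult$costs
  expect_equal(costs$direct_cost_busd2019[costs$disease_group == "CVD"], 414)
  expect_equal(costs$indirect_cost_busd2019[costs$disease_group == "CVD"], 337)
  expect_equal(costs$direct_cost_busd2019[costs$disease_group == "diabetes"], 268)
  expect_equal(costs$indirect_cost_busd2019[costs$disease_group == "diabetes"], 147)
  expect_equal(costs$direct_cost_busd2019[costs$disease_group == "cancer"], 220)
  expect_equal(costs$indirect_cost_busd2019[costs$disease_group == "cancer"], 101)
})

test_that("a config missing a stratum raises a schema error", {
  pars <- PARS
  pars$generator$adult$population_millions[["75+"]] <- NULL
  expect_error(generate_adult_inputs(seed = 1, pars = pars),
               class = "smc_schema_error")
})

test_that("parameter library validates its published inputs", {
  expect_equal(PARS$child_effects$added_sugar_bmi$point, 0.05)
  expect_equal(PARS$child_effects$sodium_sbp$point, 0.8)
  expect_equal(PARS$child_effects$sodium_dbp$point, 0.7)
  expect_equal(PARS$persistence$point, 0.35)
  expect_equal(PARS$child_effects$ssb_g_per_serving, 20.5)
  # the per-gram BMI effect is the per-serving SSB effect over 20.5 g
  expect_equal(ssb_effect_per_gram(0.05 * 20.5), 0.05)
  bad <- PARS
  bad$persistence$point <- 1.4
  expect_error(validate_parameter_library(bad), class = "smc_parameter_error")
  bad2 <- PARS
  bad2$rr_library$direct[[1]]$rr <- -0.2
  expect_error(validate_parameter_library(bad2), class = "smc_parameter_error")
})
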
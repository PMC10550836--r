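# Shared fixtures: built once per test run, in code only.

PARS <- default_parameter_library()
STANDARDS <- build_standards(PARS)
COMPLIANCE <- build_compliance_model(PARS)

# moderate population reused across tests
KIDS <- generate_child_population(2000, seed = 101, pars = PARS)

# a one-child record table for hand-arithmetic oracles
single_child_records <- function(lunch_participation = 180 / 365,
                                 breakfast_participation = 0,
                                 lunch_sodium = 900, lunch_sugar = 10,
                                 lunch_wg = 5, lunch_grain = 40,
                                 grade_band = "K5") {
  tibble::tibble(
    person_id = "C1", day = 1L, age_y = 8L, sex = "female",
    race_eth = "NH-White", grade_band = grade_band, survey_weight = 1,
    breakfast_participation = breakfast_participation,
    lunch_participation = lunch_participation,
    bmi = 17, sbp = 100, dbp = 60,
    school_breakfast_added_sugar_g = 0, school_breakfast_sodium_mg = 0,
    school_breakfast_whole_grain_g = 0, school_breakfast_total_grain_g = 0,
    school_lunch_added_sugar_g = lunch_sugar,
    school_lunch_sodium_mg = lunch_sodium,
    school_lunch_whole_grain_g = lunch_wg,
    school_lunch_total_grain_g = lunch_grain,
    other_added_sugar_g = 50, other_sodium_mg = 2000,
    other_whole_grain_g = 10, other_total_grain_g = 60
  )
}

# parameter library with every source of sampling uncertainty removed
zero_variance_pars <- function(pars = PARS) {
  for (nm in c("added_sugar_bmi", "sodium_sbp", "sodium_dbp")) {
    p <- pars$child_effects[[nm]]$point
    pars$child_effects[[nm]]$ci <- c(p, p)
  }
  for (nm in c("added_sugar_bmi", "whole_grain_bmi", "sodium_sbp")) {
    pars$adult_effects[[nm]]$log_like_se <- 0
  }
  pars$rr_library$direct <- lapply(pars$rr_library$direct, function(r) {
    r$log_se <- 0
    r
  })
  for (d in names(pars$rr_library$bmi_mediated$diseases)) {
    pars$rr_library$bmi_mediated$diseases[[d]]$log_se <- 0
  }
  for (d in names(pars$rr_library$sbp_mediated$diseases)) {
    pars$rr_library$sbp_mediated$diseases[[d]]$log_se <- 0
  }
  pars$uncertainty$rate_log_sd <- 0
  pars$uncertainty$daly_log_sd <- 0
  pars$uncertainty$cost_log_sd <- 0
  pars
}
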
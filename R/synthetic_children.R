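#' Simulate a school-aged child dietary population
#'
#' Generates NHANES-style 24-h recall microdata: one row per child per recall
#' day, with source-tagged intakes (school breakfast, school lunch, all other
#' sources) of added sugars (g), sodium (mg), whole grain (g) and total grain
#' mass (g), school-meal participation fractions, demographics, survey
#' weights, BMI and blood pressure.
#'
#' Intake amounts are lognormal (nonnegative and right-skewed, the stylised
#' shape of dietary intake data) with a person-level and a day-level variance
#' component on the log scale, so the usual-intake estimator has a true
#' between/within split to recover.  Whole grain is generated as a Beta-
#' distributed person-level share of total grain mass.  Participation is a
#' Beta-distributed per-child propensity realised as Binomial participation
#' over the school year; the stored fractions are days per calendar year.
#' School-source intakes are per participating day and are zero for children
#' who never participate in that meal.
#'
#' Per-meal means are calibrated (once, by simulation) so grade-level
#' habitual means and full-compliance intake changes sit at the configured
#' targets in the parameter file.
#'
#' @param n number of children (>= 1)
#' @param seed integer seed; identical (n, seed, pars) give identical output
#' @param pars parameter library; `generator$child` section drives generation
#' @return tibble of child-day records (class includes `smc_child_records`)
#' @examples
#' kids <- generate_child_population(200, seed = 1)
#' dplyr::count(kids, grade_band)
#' @export
generate_child_population <- function(n, seed = 1,
                                      pars = default_parameter_library()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_parameter("generate_child_population: n must be a count >= 1")
  }
  n <- as.integer(n)
  cfg <- pars$generator$child
  if (cfg$log_sd_between < 0 || cfg$log_sd_within < 0) {
    stop_parameter("dispersion parameters must be nonnegative")
  }
  withr::local_seed(as.integer(seed))

  n_days <- cfg$n_days
  sy <- cfg$school_year_days

  age_y <- sample(5:18, n, replace = TRUE)
  grade_band <- grade_band_for_age(age_y)
  sex <- sample(SEXES, n, replace = TRUE)
  race_eth <- sample(names(cfg$race_probs), n, replace = TRUE,
                     prob = unlist(cfg$race_probs))
  survey_weight <- stats::rlnorm(n, -cfg$weight_log_sd^2 / 2, cfg$weight_log_sd)

  part <- function(meal) {
    m <- unlist(cfg$participation[[meal]])[grade_band]
    conc <- cfg$participation_concentration
    prop <- stats::rbeta(n, m * conc, (1 - m) * conc)
    stats::rbinom(n, sy, prop) / 365
  }
  breakfast_participation <- part("breakfast")
  lunch_participation <- part("lunch")

  sb <- cfg$log_sd_between
  sw <- cfg$log_sd_within
  ln_adj <- (sb^2 + sw^2) / 2  # so E[exp(b + e)] adjusts to the target mean

  # lognormal person x day draws around a per-grade mean
  draw_amount <- function(mean_by_grade) {
    m <- unlist(mean_by_grade)[grade_band]
    b <- stats::rnorm(n, 0, sb)
    do.call(cbind, lapply(seq_len(n_days), function(j) {
      m * exp(b + stats::rnorm(n, 0, sw) - ln_adj)
    }))
  }

  sources <- c(breakfast = "breakfast", lunch = "lunch", other = "other")
  amounts <- list()
  for (src in names(sources)) {
    for (nut in c("added_sugar", "sodium", "total_grain")) {
      amounts[[paste(src, nut, sep = ".")]] <-
        draw_amount(cfg$meal_mean[[nut]][[src]])
    }
    share_mean <- if (src == "other") cfg$grain_share$other else cfg$grain_share$school
    conc <- cfg$grain_share$concentration
    share <- stats::rbeta(n, share_mean * conc, (1 - share_mean) * conc)
    amounts[[paste(src, "whole_grain", sep = ".")]] <-
      amounts[[paste(src, "total_grain", sep = ".")]] * share
  }

  bmi <- stats::rlnorm(n, log(16.5 + 0.45 * (age_y - 5)), 0.15)
  sbp <- stats::rnorm(n, 97 + 0.8 * age_y, 8)
  dbp <- stats::rnorm(n, 57 + 0.4 * age_y, 7)

  person <- tibble::tibble(
    person_id = sprintf("C%06d", seq_len(n)),
    age_y = age_y, sex = sex, race_eth = race_eth, grade_band = grade_band,
    survey_weight = survey_weight,
    breakfast_participation = breakfast_participation,
    lunch_participation = lunch_participation,
    bmi = bmi, sbp = sbp, dbp = dbp
  )

  out <- tidyr::crossing(person, day = seq_len(n_days)) |>
    dplyr::arrange(.data$person_id, .data$day)
  idx <- cbind(rep(seq_len(n), each = n_days), rep(seq_len(n_days), times = n))
  col_name <- function(src, nut) {
    prefix <- c(breakfast = "school_breakfast", lunch = "school_lunch",
                other = "other")[[src]]
    suffix <- c(added_sugar = "added_sugar_g", sodium = "sodium_mg",
                whole_grain = "whole_grain_g", total_grain = "total_grain_g")[[nut]]
    paste(prefix, suffix, sep = "_")
  }
  for (src in names(sources)) {
    pcol <- switch(src, breakfast = out$breakfast_participation,
                   lunch = out$lunch_participation, other = NULL)
    for (nut in c("added_sugar", "sodium", "whole_grain", "total_grain")) {
      v <- amounts[[paste(src, nut, sep = ".")]][idx]
      if (!is.null(pcol)) v[pcol == 0] <- 0  # never-participants eat no school food
      out[[col_name(src, nut)]] <- v
    }
  }
  class(out) <- c("smc_child_records", class(out))
  out
}

#' Collapse child-day records to one row per child
#'
#' Averages the per-day intake columns within person; demographic and
#' participation columns are constant within person and carried through.
#' @param records child-day records from [generate_child_population()]
#' @return tibble with one row per person
#' @export
collapse_child_days <- function(records) {
  intake_cols <- grep("_(g|mg)$", names(records), value = TRUE)
  records |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("age_y", "survey_weight",
                                    "breakfast_participation",
                                    "lunch_participation", "bmi", "sbp", "dbp")),
                    dplyr::first),
      dplyr::across(dplyr::all_of(c("sex", "race_eth", "grade_band")), dplyr::first),
      dplyr::across(dplyr::all_of(intake_cols), mean),
      .groups = "drop"
    )
}

#' Habitual daily intake of one factor, per child
#'
#' Habitual daily intake = other-source intake plus each school meal's
#' per-participating-day intake weighted by the participation fraction
#' (days per calendar year).
#' @param children one-row-per-child table ([collapse_child_days()])
#' @param factor `"added_sugar"`, `"sodium"` or `"whole_grain"`
#' @return numeric vector, one value per child
#' @export
habitual_daily_intake <- function(children, factor) {
  suffix <- c(added_sugar = "added_sugar_g", sodium = "sodium_mg",
              whole_grain = "whole_grain_g")[[factor]]
  if (is.na(suffix)) stop_parameter("unknown factor: ", factor)
  children[[paste0("other_", suffix)]] +
    children$breakfast_participation * children[[paste0("school_breakfast_", suffix)]] +
    children$lunch_participation * children[[paste0("school_lunch_", suffix)]]
}
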
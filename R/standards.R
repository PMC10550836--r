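#' Per-meal added-sugar limit from a calorie allowance
#'
#' The 2020-2025 DGA allows at most 10% of energy from added sugars.  The
#' per-meal gram limit is `calorie_allowance * energy_fraction / kcal_per_g`,
#' reported to one decimal (half-up).
#'
#' @param calorie_allowance kcal planned for the meal
#' @param energy_fraction share of energy allowed from added sugars (0.10)
#' @param kcal_per_g energy density of sugar (4 kcal/g)
#' @return limit in g/meal
#' @examples
#' added_sugar_limit(500)  # 12.5 (K-5 breakfast)
#' added_sugar_limit(600)  # 15.0 (9-12 breakfast)
#' @export
added_sugar_limit <- function(calorie_allowance, energy_fraction = 0.10,
                              kcal_per_g = 4) {
  if (any(c(calorie_allowance, energy_fraction, kcal_per_g) <= 0)) {
    stop_parameter("added_sugar_limit: all arguments must be positive")
  }
  round_half_up(calorie_allowance * energy_fraction / kcal_per_g, 1)
}

#' Per-meal sodium limit from the CDRR
#'
#' The Chronic Disease Risk Reduction (CDRR) daily sodium amount for the
#' grade band's age group is multiplied by the share of daily calories the
#' meal contributes, then rounded to the nearest 10 mg.
#'
#' @param cdrr_mg daily CDRR sodium amount, mg
#' @param meal_calorie_fraction share of daily calories from the meal, in (0, 1)
#' @return limit in mg/meal
#' @examples
#' sodium_limit(1500, 0.34)    # 510 (K-5 lunch)
#' sodium_limit(2300, 0.2174)  # 500 (9-12 breakfast)
#' @export
sodium_limit <- function(cdrr_mg, meal_calorie_fraction) {
  if (any(cdrr_mg <= 0)) stop_parameter("sodium_limit: cdrr_mg must be positive")
  if (any(meal_calorie_fraction <= 0 | meal_calorie_fraction >= 1)) {
    stop_parameter("sodium_limit: meal_calorie_fraction must lie in (0, 1)")
  }
  round_half_up(cdrr_mg * meal_calorie_fraction, -1)
}

#' Build the full DGA-aligned standards table
#'
#' One row per grade band and meal with the added-sugar limit (g/meal), the
#' sodium limit (mg/meal), and the whole-grain-rich mass fraction required of
#' grain foods.  Default configuration reproduces the published limits:
#' added sugars 12.5/13.8/15 g (breakfast) and 16.3/17.5/21 g (lunch);
#' sodium 340/390/500 mg (breakfast) and 510/580/740 mg (lunch) for grades
#' K-5, 6-8, 9-12.  The 9-12 lunch added-sugar cell is a per-cell override
#' (the published table floors it to 21 g where the general rounding rule
#' would give 21.3).
#'
#' @param pars parameter library (see [default_parameter_library()]); only
#'   the `standards` section is used
#' @return tibble: grade_band, meal, added_sugar_max_g, sodium_max_mg,
#'   whole_grain_rich_fraction
#' @examples
#' build_standards()
#' @export
build_standards <- function(pars = default_parameter_library()) {
  cfg <- pars$standards
  grid <- tidyr::crossing(meal = MEALS, grade_band = GRADE_BANDS)
  for (m in MEALS) {
    for (g in GRADE_BANDS) {
      if (is.null(cfg$calorie_allowance_kcal[[m]][[g]]) ||
          is.null(cfg$meal_calorie_fraction[[m]][[g]])) {
        stop_schema("standards config missing ", m, " allowance/fraction for grade ", g)
      }
      if (is.null(cfg$cdrr_mg[[g]])) stop_schema("standards config missing CDRR for grade ", g)
    }
  }
  out <- grid |>
    dplyr::rowwise() |>
    dplyr::mutate(
      added_sugar_max_g = added_sugar_limit(
        cfg$calorie_allowance_kcal[[.data$meal]][[.data$grade_band]],
        cfg$energy_fraction_added_sugar, cfg$kcal_per_g_sugar),
      sodium_max_mg = sodium_limit(
        cfg$cdrr_mg[[.data$grade_band]],
        cfg$meal_calorie_fraction[[.data$meal]][[.data$grade_band]]),
      whole_grain_rich_fraction = cfg$whole_grain_rich_fraction
    ) |>
    dplyr::ungroup()
  for (ov in cfg$added_sugar_overrides) {
    hit <- out$meal == ov$meal & out$grade_band == ov$grade_band
    out$added_sugar_max_g[hit] <- ov$value
  }
  out |>
    dplyr::mutate(grade_band = factor(.data$grade_band, levels = GRADE_BANDS)) |>
    dplyr::arrange(.data$meal, .data$grade_band) |>
    dplyr::mutate(grade_band = as.character(.data$grade_band))
}

#' Standards table in long (factor, limit) layout
#'
#' Companion layout for file exchange: one row per (grade_band, meal, factor)
#' with the limit and its unit.  Whole grain is expressed as the required
#' whole-grain mass fraction.
#' @param standards wide table from [build_standards()]
#' @return tibble: grade_band, meal, factor, limit, unit
#' @export
standards_long <- function(standards) {
  dplyr::bind_rows(
    dplyr::transmute(standards, .data$grade_band, .data$meal,
                     factor = "added_sugar", limit = .data$added_sugar_max_g,
                     unit = "g/meal"),
    dplyr::transmute(standards, .data$grade_band, .data$meal,
                     factor = "sodium", limit = .data$sodium_max_mg,
                     unit = "mg/meal"),
    dplyr::transmute(standards, .data$grade_band, .data$meal,
                     factor = "whole_grain", limit = .data$whole_grain_rich_fraction,
                     unit = "fraction of grain mass")
  )
}
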
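#' Estimate usual intake by stratum
#'
#' Usual (long-run habitual) intake is estimated from 1-2 recall days per
#' person with a two-component method-of-moments variance split on the log
#' scale: the within-person (day-to-day) variance is the mean of per-person
#' sample variances across repeat days, and the between-person variance is
#' the variance of person means minus the within-person contribution
#' `sigma2_w * mean(1/k_i)` (clamped at zero).  The stratum usual mean is
#' the survey-weighted mean of person-level mean intakes on the natural
#' scale.  When no person has repeat days the within-person variance is set
#' to zero with a warning (no shrinkage is then possible).  This is a
#' deliberate simplification of the full NCI mixed-model method: downstream
#' stages consume only stratum means and variances.
#'
#' @param records child-day records ([generate_child_population()])
#' @param factor dietary factor (`"added_sugar"`, `"sodium"`, `"whole_grain"`)
#' @param strata character vector of stratification columns
#'   (default `"grade_band"`)
#' @return tibble per stratum: distribution family, usual mean and SE,
#'   between/within log-scale variances, person count
#' @export
estimate_usual_intake <- function(records, factor, strata = "grade_band") {
  day_values <- records |>
    dplyr::mutate(.value = habitual_daily_intake(records, factor))
  sizes <- dplyr::count(day_values, dplyr::across(dplyr::all_of(strata)))
  if (any(sizes$n < 2)) {
    small <- sizes[sizes$n < 2, strata, drop = FALSE]
    stop_estimation("usual-intake stratum too small: ",
                    paste(apply(small, 1, paste, collapse = "/"),
                          collapse = ", "))
  }
  out <- day_values |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::group_modify(function(df, key) {
      per_person <- df |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(
          w = dplyr::first(.data$survey_weight),
          m = mean(.data$.value),
          k = dplyr::n(),
          s2_log = if (dplyr::n() > 1 && all(.data$.value > 0)) {
            stats::var(log(.data$.value))
          } else NA_real_,
          m_log = if (all(.data$.value > 0)) mean(log(.data$.value)) else NA_real_,
          .groups = "drop"
        )
      wm <- weighted_mean_se(per_person$m, per_person$w)
      repeats <- !is.na(per_person$s2_log)
      if (any(repeats)) {
        var_within <- mean(per_person$s2_log[repeats])
      } else {
        rlang::warn("no repeat recall days in stratum; within-person variance set to 0")
        var_within <- 0
      }
      var_means <- if (all(!is.na(per_person$m_log))) {
        stats::var(per_person$m_log)
      } else {
        stats::var(log(pmax(per_person$m, 1e-9)))
      }
      var_between <- max(var_means - var_within * mean(1 / per_person$k), 0)
      tibble::tibble(
        factor = factor, distribution = "lognormal",
        mean = wm$mean, se_mean = wm$se,
        var_between = var_between, var_within = var_within,
        n_persons = nrow(per_person)
      )
    }) |>
    dplyr::ungroup()
  out
}

#' Expand the compliance model to one row per (factor, meal, grade band)
#'
#' Plate-waste fractions and noncompliance rates default per factor and can
#' be overridden per (factor, meal, grade_band) through the parameter file's
#' `compliance$overrides` list.
#' @param pars parameter library
#' @return tibble: factor, meal, grade_band, waste_fraction, noncompliance
#' @export
build_compliance_model <- function(pars = default_parameter_library()) {
  cfg <- pars$compliance
  out <- tidyr::crossing(factor = DIET_FACTORS, meal = MEALS,
                         grade_band = GRADE_BANDS) |>
    dplyr::mutate(
      waste_fraction = unlist(cfg$waste_fraction)[.data$factor],
      noncompliance = unlist(cfg$noncompliance)[.data$factor]
    )
  for (ov in cfg$overrides) {
    hit <- out$factor == ov$factor & out$meal == ov$meal &
      out$grade_band == ov$grade_band
    if (!any(hit)) stop_schema("compliance override matches no cell")
    if (!is.null(ov$waste_fraction)) out$waste_fraction[hit] <- ov$waste_fraction
    if (!is.null(ov$noncompliance)) out$noncompliance[hit] <- ov$noncompliance
  }
  bad <- out$waste_fraction < 0 | out$waste_fraction >= 1 |
    out$noncompliance < 0 | out$noncompliance > 1
  if (any(bad)) stop_parameter("compliance model outside valid ranges")
  out
}

#' Counterfactual consumed amount under a new per-meal standard
#'
#' Vectorised core of the counterfactual construction.  Limits apply to
#' offered food; children waste a fraction `w` of what is offered, so the
#' binding comparison for consumed amounts is against `limit * (1 - w)`.
#' For added sugars and sodium the counterfactual is
#' `min(consumed, limit * (1 - w))` -- schools are conservatively assumed
#' never to cut below the target, and meals already under the limit are not
#' raised to it.  For whole grains the standard is a floor:
#' `max(consumed, f_wgr * total_grain * (1 - w))`, where `f_wgr` is the
#' whole-grain-rich mass fraction required of grain foods.  Under partial
#' compliance a school fails to comply with probability `p`, applied as an
#' expectation: `p * consumed + (1 - p) * counterfactual`.
#'
#' @param consumed consumed amount at the meal (g or mg)
#' @param limit per-meal limit (ignored for whole grain)
#' @param factor dietary factor
#' @param waste_fraction plate-waste fraction in [0, 1)
#' @param noncompliance probability of noncompliance in [0, 1]
#' @param scenario `"full"` or `"partial"`
#' @param total_grain grain mass consumed at the meal (whole grain only)
#' @param whole_grain_rich_fraction required whole-grain mass fraction
#' @return counterfactual consumed amount(s)
#' @examples
#' counterfactual_intake(900, 510, "sodium", waste_fraction = 0.1)  # 459
#' @export
counterfactual_intake <- function(consumed, limit, factor,
                                  waste_fraction = 0, noncompliance = 0,
                                  scenario = c("full", "partial"),
                                  total_grain = NULL,
                                  whole_grain_rich_fraction = 0.5) {
  scenario <- match.arg(scenario)
  if (any(waste_fraction < 0 | waste_fraction >= 1)) {
    stop_parameter("waste_fraction must lie in [0, 1)")
  }
  if (factor == "whole_grain") {
    if (is.null(total_grain)) {
      stop_contract("whole-grain counterfactual requires total_grain mass")
    }
    target <- whole_grain_rich_fraction * total_grain * (1 - waste_fraction)
    cf <- pmax(consumed, target)
  } else {
    cf <- pmin(consumed, limit * (1 - waste_fraction))
  }
  if (scenario == "partial") {
    cf <- noncompliance * consumed + (1 - noncompliance) * cf
  }
  cf
}

#' Counterfactual school-meal intake for one child record
#'
#' Applies [counterfactual_intake()] to every dietary factor at one school
#' meal of a single child record, under a matching `MealStandard` row.
#' @param record one-row child table (person level)
#' @param standard one row of [build_standards()]
#' @param compliance compliance table from [build_compliance_model()]
#' @param scenario `"full"` or `"partial"`
#' @return tibble: factor, consumed, counterfactual
#' @export
counterfactual_meal_intake <- function(record, standard, compliance,
                                       scenario = c("full", "partial")) {
  scenario <- match.arg(scenario)
  if (nrow(record) != 1 || nrow(standard) != 1) {
    stop_contract("counterfactual_meal_intake expects single rows")
  }
  if (record$grade_band != standard$grade_band) {
    stop_contract("record grade band (", record$grade_band,
                  ") does not match standard (", standard$grade_band, ")")
  }
  meal <- standard$meal
  prefix <- if (meal == "breakfast") "school_breakfast_" else "school_lunch_"
  suffix <- c(added_sugar = "added_sugar_g", sodium = "sodium_mg",
              whole_grain = "whole_grain_g")
  purrr::map_dfr(DIET_FACTORS, function(f) {
    comp <- compliance[compliance$factor == f & compliance$meal == meal &
                         compliance$grade_band == standard$grade_band, ]
    if (nrow(comp) != 1) stop_schema("compliance cell missing for ", f, "/", meal)
    consumed <- record[[paste0(prefix, suffix[[f]])]]
    limit <- switch(f, added_sugar = standard$added_sugar_max_g,
                    sodium = standard$sodium_max_mg, whole_grain = NA_real_)
    tibble::tibble(
      factor = f, meal = meal, consumed = consumed,
      counterfactual = counterfactual_intake(
        consumed, limit, f, comp$waste_fraction, comp$noncompliance, scenario,
        total_grain = record[[paste0(prefix, "total_grain_g")]],
        whole_grain_rich_fraction = standard$whole_grain_rich_fraction)
    )
  })
}

#' Habitual daily intake changes under the new standards
#'
#' The Table-2 engine.  Per child, the change in habitual daily intake of a
#' factor is the sum over school meals of the participation fraction (days
#' per calendar year) times the per-participating-day change
#' `counterfactual - consumed`.  Stratum-level changes are survey-weighted
#' means with weighted-mean SEs, and percent change is taken against the
#' stratum baseline habitual mean.
#'
#' @param records child-day records
#' @param standards table from [build_standards()]
#' @param compliance table from [build_compliance_model()]
#' @param scenario `"full"` (all schools comply) or `"partial"`
#' @param strata stratification columns (default grade band only, the
#'   published collapse; add `"race_eth"` for grade x race output)
#' @return tibble: stratum, factor, scenario, baseline_mean, baseline_se,
#'   delta_mean, se_delta, percent_change
#' @export
habitual_change <- function(records, standards, compliance,
                            scenario = c("full", "partial"),
                            strata = "grade_band") {
  scenario <- match.arg(scenario)
  if (!all(GRADE_BANDS %in% standards$grade_band)) {
    stop_schema("standards must cover all grade bands")
  }
  children <- collapse_child_days(records)
  suffix <- c(added_sugar = "added_sugar_g", sodium = "sodium_mg",
              whole_grain = "whole_grain_g")

  lim <- function(meal, f) {
    col <- switch(f, added_sugar = "added_sugar_max_g", sodium = "sodium_max_mg",
                  whole_grain = NA_character_)
    if (is.na(col)) return(rep(NA_real_, nrow(children)))
    s <- standards[standards$meal == meal, ]
    stats::setNames(s[[col]], s$grade_band)[children$grade_band]
  }
  wgr <- {
    s <- standards[standards$meal == "lunch", ]
    stats::setNames(s$whole_grain_rich_fraction, s$grade_band)[children$grade_band]
  }
  comp_val <- function(meal, f, what) {
    c0 <- compliance[compliance$meal == meal & compliance$factor == f, ]
    stats::setNames(c0[[what]], c0$grade_band)[children$grade_band]
  }

  purrr::map_dfr(DIET_FACTORS, function(f) {
    delta <- rep(0, nrow(children))
    for (meal in MEALS) {
      prefix <- if (meal == "breakfast") "school_breakfast_" else "school_lunch_"
      consumed <- children[[paste0(prefix, suffix[[f]])]]
      cf <- counterfactual_intake(
        consumed, lim(meal, f), f,
        waste_fraction = comp_val(meal, f, "waste_fraction"),
        noncompliance = comp_val(meal, f, "noncompliance"),
        scenario = scenario,
        total_grain = children[[paste0(prefix, "total_grain_g")]],
        whole_grain_rich_fraction = wgr)
      pcol <- if (meal == "breakfast") children$breakfast_participation else
        children$lunch_participation
      delta <- delta + pcol * (cf - consumed)
    }
    children |>
      dplyr::mutate(.delta = delta,
                    .baseline = habitual_daily_intake(children, f)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
      dplyr::group_modify(function(df, key) {
        d <- weighted_mean_se(df$.delta, df$survey_weight)
        b <- weighted_mean_se(df$.baseline, df$survey_weight)
        tibble::tibble(
          factor = f, scenario = scenario,
          baseline_mean = b$mean, baseline_se = b$se,
          delta_mean = d$mean, se_delta = d$se,
          percent_change = percent_change(d$mean, b$mean)
        )
      }) |>
      dplyr::ungroup()
  })
}

#' Percent change of a habitual intake delta against baseline
#'
#' `100 * delta / baseline`, reported to one decimal (half-up).  Numerator
#' and denominator are used at full precision.
#' @param delta signed change
#' @param baseline baseline mean (> 0)
#' @return signed percent, one decimal
#' @examples
#' percent_change(-2.72, 69.5)  # -3.9
#' percent_change(7.29, 27.3)   # 26.7
#' @export
percent_change <- function(delta, baseline) {
  if (any(baseline <= 0)) stop_parameter("percent_change: baseline must be positive")
  round_half_up(100 * delta / baseline, 1)
}
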
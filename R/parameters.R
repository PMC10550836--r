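#' Load the default parameter library
#'
#' Reads the packaged parameter file covering every model input: per-meal
#' standards inputs (calorie allowances, sodium CDRR values, meal calorie
#' fractions), plate-waste and noncompliance rates, child diet-to-risk-factor
#' effect sizes with 95% CIs, the adulthood persistence fraction, national
#' disease cost totals, synthetic-data generation parameters, adult mediator
#' effects, and the adult relative-risk library.  Adult relative risks and
#' mediator effects default to literature-plausible placeholder values and
#' are tagged `source: placeholder` in the file; the adult model is assessed
#' by structural properties, never by those values.
#'
#' @param path optional path to an alternative YAML parameter file
#' @return a nested list (class `smc_parameters`) mirroring the YAML layout
#' @examples
#' pars <- default_parameter_library()
#' pars$child_effects$added_sugar_bmi$point  # 0.05 kg/m2 per g/d
#' pars$persistence$point                    # 0.35
#' @export
default_parameter_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_parameters.yaml",
                        package = "schoolmealcra", mustWork = TRUE)
  }
  pars <- yaml::read_yaml(path)
  validate_parameter_library(pars)
  structure(pars, class = c("smc_parameters", "list"))
}

#' Validate a parameter library
#'
#' Checks the invariants the pipeline relies on: every relative risk > 0,
#' every SE >= 0, persistence in [0, 1], waste fractions in [0, 1),
#' noncompliance rates in [0, 1], costs nonnegative, and CI bounds that
#' bracket their point estimates.
#' @param pars nested parameter list
#' @return the library, invisibly, or an error
#' @export
validate_parameter_library <- function(pars) {
  need <- c("standards", "compliance", "child_effects", "persistence",
            "costs_busd2019", "generator", "adult_effects", "rr_library",
            "uncertainty")
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop_schema("parameter library missing sections: ",
                paste(missing, collapse = ", "))
  }
  k <- pars$persistence$point
  if (!is.numeric(k) || k < 0 || k > 1) {
    stop_parameter("persistence fraction must lie in [0, 1], got ", k)
  }
  for (f in DIET_FACTORS) {
    w <- pars$compliance$waste_fraction[[f]]
    p <- pars$compliance$noncompliance[[f]]
    if (w < 0 || w >= 1) stop_parameter("waste fraction for ", f, " outside [0, 1)")
    if (p < 0 || p > 1) stop_parameter("noncompliance rate for ", f, " outside [0, 1]")
  }
  for (nm in names(pars$child_effects)) {
    eff <- pars$child_effects[[nm]]
    if (!is.list(eff) || is.null(eff$ci)) next
    if (eff$ci[1] > eff$point || eff$ci[2] < eff$point) {
      stop_parameter("child effect ", nm, ": CI does not contain the point estimate")
    }
  }
  for (row in pars$rr_library$direct) {
    if (row$rr <= 0) stop_parameter("relative risk must be positive: ",
                                    row$factor, "/", row$disease)
    if (row$log_se < 0) stop_parameter("log-RR SE must be nonnegative")
  }
  for (cost in pars$costs_busd2019) {
    if (cost$direct < 0 || cost$indirect < 0) stop_parameter("costs must be nonnegative")
  }
  invisible(pars)
}

#' Child effect specification as a one-row tibble
#'
#' @param pars parameter library
#' @param name one of `"added_sugar_bmi"`, `"sodium_sbp"`, `"sodium_dbp"`
#' @return tibble with point, CI bounds, SE (CI width / 3.92), exposure
#'   divisor and outcome label
#' @export
child_effect_spec <- function(pars, name) {
  eff <- pars$child_effects[[name]]
  if (is.null(eff) || !is.list(eff)) stop_parameter("unknown child effect: ", name)
  outcome <- switch(name,
    added_sugar_bmi = "BMI", sodium_sbp = "SBP", sodium_dbp = "DBP",
    stop_parameter("unknown child effect: ", name))
  tibble::tibble(
    effect = name,
    outcome = outcome,
    factor = if (outcome == "BMI") "added_sugar" else "sodium",
    point = eff$point,
    ci_low = eff$ci[1],
    ci_high = eff$ci[2],
    se = se_from_ci(eff$ci[1], eff$ci[2]),
    per = eff$per
  )
}

#' Convert a per-serving SSB effect to a per-gram added-sugar effect
#'
#' The childhood BMI evidence base is randomized trials of sugar-sweetened
#' beverage (SSB) servings; the model works in grams of added sugar.  The
#' conversion divides the per-serving effect by the average added-sugar
#' content of an 8-oz serving (default 20.5 g).
#'
#' @param per_serving_effect effect per 8-oz SSB serving
#' @param g_per_serving grams added sugar per serving
#' @return effect per gram of added sugar per day
#' @examples
#' ssb_effect_per_gram(1.025, 20.5)  # 0.05
#' @export
ssb_effect_per_gram <- function(per_serving_effect, g_per_serving = 20.5) {
  if (g_per_serving <= 0) stop_parameter("g_per_serving must be positive")
  per_serving_effect / g_per_serving
}

#' Expand the relative-risk library into a long table
#'
#' Applies the age-specific log-RR multipliers to every base RR, yielding one
#' row per (factor, disease, path, age band).  Mediated paths are expanded to
#' the diseases they touch: the BMI path to CHD, stroke, diabetes and each
#' obesity-related cancer site; the SBP path to CHD and stroke (or stroke
#' only when `rr_library$sbp_mediated$stroke_only` is set).
#'
#' @param pars parameter library
#' @return tibble: factor, disease, path, age_band, rr_per_unit, per, log_se
#' @export
expand_rr_library <- function(pars) {
  lib <- pars$rr_library
  agem <- unlist(lib$age_log_multiplier)
  if (length(agem) != length(AGE_BANDS)) {
    stop_schema("age_log_multiplier must have ", length(AGE_BANDS), " entries")
  }
  base <- dplyr::bind_rows(
    purrr::map_dfr(lib$direct, ~ tibble::tibble(
      factor = .x$factor, disease = .x$disease, path = "direct",
      rr_base = .x$rr, per = .x$per, log_se = .x$log_se,
      rr_key = paste("direct", .x$factor, .x$disease, sep = ".")
    )),
    mediated_base_rows(pars)
  )
  tidyr::crossing(base,
                  tibble::tibble(age_band = AGE_BANDS, age_mult = agem)) |>
    dplyr::mutate(rr_per_unit = exp(log(.data$rr_base) * .data$age_mult)) |>
    dplyr::select("factor", "disease", "path", "age_band", "rr_base",
                  "age_mult", "rr_per_unit", "per", "log_se", "rr_key")
}

# mediated paths as base rows (mediator -> disease RRs, tagged by path);
# the diet -> mediator leg lives in adult_effects.  Obesity-related cancer
# sites share one BMI-RR spec, so they share one sampling key (rr_key).
mediated_base_rows <- function(pars) {
  lib <- pars$rr_library
  bmi <- lib$bmi_mediated
  bmi_diseases <- c("CHD", "stroke", "diabetes", bmi$obesity_related_cancers)
  bmi_rows <- purrr::map_dfr(bmi_diseases, function(d) {
    spec_name <- if (startsWith(d, "cancer_")) "cancer_obesity_related" else d
    spec <- bmi$diseases[[spec_name]]
    tibble::tibble(factor = unlist(lib$mediated_factors$bmi), disease = d,
                   path = "bmi_mediated", rr_base = spec$rr, per = bmi$per,
                   log_se = spec$log_se,
                   rr_key = paste("bmi", spec_name, sep = "."))
  })
  sbp <- lib$sbp_mediated
  sbp_diseases <- if (isTRUE(sbp$stroke_only)) "stroke" else unlist(sbp$applies_to)
  sbp_rows <- purrr::map_dfr(sbp_diseases, function(d) {
    spec <- sbp$diseases[[d]]
    tibble::tibble(factor = unlist(lib$mediated_factors$sbp), disease = d,
                   path = "sbp_mediated", rr_base = spec$rr, per = sbp$per,
                   log_se = spec$log_se,
                   rr_key = paste("sbp", d, sep = "."))
  })
  dplyr::bind_rows(bmi_rows, sbp_rows)
}

#' Disease group for burden and cost aggregation
#'
#' CHD and stroke roll up to CVD; every `cancer_*` mortality stream rolls up
#' to cancer; diabetes stands alone.
#' @param disease character vector of disease codes
#' @return character vector of groups (`"CVD"`, `"diabetes"`, `"cancer"`)
#' @export
disease_group <- function(disease) {
  dplyr::case_when(
    disease %in% c("CHD", "stroke") ~ "CVD",
    disease == "diabetes" ~ "diabetes",
    startsWith(disease, "cancer_") ~ "cancer",
    TRUE ~ NA_character_
  )
}
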
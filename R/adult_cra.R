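#' Persist childhood dietary change into adulthood
#'
#' The counterfactual assumes current adults experienced the new standards at
#' school age: a fraction `kappa` (base case 0.35, sensitivity 0.25/0.50) of
#' the population-weighted mean childhood habitual change carries into every
#' adult age band.  Linear in `kappa`.
#'
#' @param child_changes intake-change table from [habitual_change()]
#'   (grade-band stratified, one scenario)
#' @param kappa persistence fraction in [0, 1]
#' @param grade_weights named vector of population shares per grade band
#'   (e.g. from [grade_population_shares()]); equal weights if `NULL`
#' @return named numeric: adult daily intake change per factor
#' @examples
#' # single-grade example: -165 mg/d sodium at kappa = 0.35 -> -57.75 mg/d
#' @export
persist_change <- function(child_changes, kappa = 0.35, grade_weights = NULL) {
  if (!is.numeric(kappa) || kappa < 0 || kappa > 1) {
    stop_parameter("kappa must lie in [0, 1]")
  }
  if (is.null(child_changes) || nrow(child_changes) == 0) {
    stop_contract("persist_change: empty child change table")
  }
  if (is.null(grade_weights)) {
    gb <- unique(child_changes$grade_band)
    grade_weights <- stats::setNames(rep(1 / length(gb), length(gb)), gb)
  }
  out <- child_changes |>
    dplyr::mutate(w = grade_weights[.data$grade_band]) |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(delta = kappa * sum(.data$w * .data$delta_mean) / sum(.data$w),
                     .groups = "drop")
  stats::setNames(out$delta, out$factor)
}

#' Population share of each grade band
#'
#' Survey-weighted share of children per grade band, used to weight grade
#' deltas when persisting childhood change into adulthood.
#' @param records child-day records
#' @return named numeric summing to 1
#' @export
grade_population_shares <- function(records) {
  kids <- dplyr::distinct(records, .data$person_id, .data$grade_band,
                          .data$survey_weight)
  sh <- tapply(kids$survey_weight, kids$grade_band, sum)
  sh <- sh / sum(sh)
  stats::setNames(as.numeric(sh), names(sh))
}

#' Relative-risk multiplier for an exposure change
#'
#' Log-linear dose response: `exp(beta * delta)` with
#' `beta = log(rr_per_unit) / per`.
#' @param rr_per_unit relative risk per `per` units of exposure (> 0)
#' @param delta exposure change, same units as `per`
#' @param per exposure unit the RR refers to (e.g. 50 g/d, 1000 mg/d)
#' @return RR multiplier
#' @examples
#' relative_risk_for_change(1.2, -50, per = 50)  # 1/1.2
#' @export
relative_risk_for_change <- function(rr_per_unit, delta, per = 1) {
  if (any(rr_per_unit <= 0)) stop_parameter("rr_per_unit must be positive")
  if (any(per <= 0)) stop_parameter("exposure unit must be positive")
  exp(log(rr_per_unit) / per * delta)
}

#' Mediated relative-risk multiplier
#'
#' Chains a diet-to-mediator effect with a mediator-to-disease RR:
#' `delta_mediator = delta_diet * effect`, then `exp(beta_m * delta_mediator)`.
#' When a modifier table is supplied (e.g. weight status for the BMI path,
#' hypertension status for the BP path) the population RR is the
#' prevalence-weighted blend of stratum RRs; `effect_mult` scales the
#' mediator change and `log_rr_mult` scales the mediator log-RR within each
#' stratum.  Direct cohort RRs are adjusted for BMI and BP, so multiplying
#' direct and mediated multipliers does not double-count.
#'
#' @param effect diet-to-mediator effect (mediator units per diet unit)
#' @param rr_per_unit mediator-to-disease RR per `per` mediator units
#' @param delta_diet dietary change (diet units)
#' @param per mediator unit of the RR (e.g. 5 kg/m2, 10 mm Hg)
#' @param modifiers optional tibble: prevalence, effect_mult, log_rr_mult
#' @return blended RR multiplier
#' @examples
#' mediated_relative_risk(0.01, 1.25, -50, per = 5)  # via delta_BMI = -0.5
#' @export
mediated_relative_risk <- function(effect, rr_per_unit, delta_diet, per,
                                   modifiers = NULL) {
  if (any(rr_per_unit <= 0)) stop_parameter("rr_per_unit must be positive")
  if (is.null(modifiers)) {
    modifiers <- tibble::tibble(prevalence = 1, effect_mult = 1, log_rr_mult = 1)
  }
  if (!all(c("prevalence") %in% names(modifiers))) {
    stop_contract("modifier table needs a prevalence column")
  }
  if (!"effect_mult" %in% names(modifiers)) modifiers$effect_mult <- 1
  if (!"log_rr_mult" %in% names(modifiers)) modifiers$log_rr_mult <- 1
  if (abs(sum(modifiers$prevalence) - 1) > 1e-8) {
    stop_contract("modifier prevalences must sum to 1")
  }
  Reduce(`+`, lapply(seq_len(nrow(modifiers)), function(i) {
    dm <- delta_diet * effect * modifiers$effect_mult[i]
    modifiers$prevalence[i] *
      exp(log(rr_per_unit) * modifiers$log_rr_mult[i] / per * dm)
  }))
}

#' Potential impact fraction from a total RR multiplier
#'
#' Under a log-linear dose response and a uniform shift of the whole intake
#' distribution, the distributional PIF collapses to `1 - rr_total`.
#' Negative values (harmful shifts) are allowed.
#' @param rr_total combined RR multiplier for the exposure change (> 0)
#' @return PIF in (-Inf, 1)
#' @examples
#' pif_for_factor(0.8333)  # ~0.1667
#' @export
pif_for_factor <- function(rr_total) {
  if (any(rr_total <= 0)) stop_parameter("rr_total must be positive")
  1 - rr_total
}

#' Distributional PIF by numerical integration (oracle)
#'
#' Computes `1 - E[RR(X + delta)] / E[RR(X)]` for a (truncated) lognormal
#' baseline intake distribution and log-linear RR, by numerical integration.
#' Under a uniform shift the result equals the closed form
#' `1 - exp(beta*delta)` for any baseline distribution; retained as an
#' independent check on the closed-form engine.  The baseline is truncated
#' at extreme quantiles (real intake distributions are bounded, and the
#' exponential moment of an untruncated lognormal diverges for positive
#' `beta`); the uniform-shift identity is unaffected by truncation.
#' @param beta log-RR per exposure unit
#' @param delta uniform exposure shift
#' @param meanlog,sdlog baseline lognormal parameters
#' @param trunc_q tail probability mass removed at each end
#' @return PIF
#' @export
pif_distributional <- function(beta, delta, meanlog = 0, sdlog = 0.5,
                               trunc_q = 1e-9) {
  lo <- stats::qlnorm(trunc_q, meanlog, sdlog)
  hi <- stats::qlnorm(1 - trunc_q, meanlog, sdlog)
  num <- stats::integrate(function(x) exp(beta * (x + delta)) *
                            stats::dlnorm(x, meanlog, sdlog),
                          lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(function(x) exp(beta * x) *
                            stats::dlnorm(x, meanlog, sdlog),
                          lo, hi, rel.tol = 1e-12, abs.tol = 0)$value
  1 - num / den
}

#' Joint multiplicative potential impact fraction
#'
#' `1 - prod(1 - PIF_f)` across risk factors; order-invariant.
#' @param pifs numeric vector of per-factor PIFs (each <= 1)
#' @return joint PIF
#' @examples
#' joint_pif(c(0.1, 0.2))  # 0.28
#' @export
joint_pif <- function(pifs) {
  if (any(pifs > 1)) stop_contract("PIF cannot exceed 1")
  1 - prod(1 - pifs)
}

#' Per-stratum potential impact fractions for the adult model
#'
#' Combines, for each (disease, age band, race/ethnicity) cell, the direct
#' and mediated RR multipliers of every dietary factor into per-factor PIFs
#' and the joint multiplicative PIF.  Race enters through the sodium-to-SBP
#' effect pattern only; other paths are race-invariant.
#'
#' @param deltas named numeric of adult intake changes (g/d or mg/d) per
#'   factor, from [persist_change()]
#' @param pars parameter library
#' @param rr_tab expanded RR table from [expand_rr_library()] (precompute
#'   when calling repeatedly)
#' @param rr_z named numeric of standard-normal log-RR perturbations keyed
#'   by `rr_key` (Monte Carlo draws); zero when `NULL`
#' @param effect_draw named list overriding adult mediator effect points
#'   (`added_sugar_bmi`, `whole_grain_bmi`, `sodium_sbp`)
#' @return tibble: disease, age_band, race_eth, factor, rr_total, pif,
#'   plus `pif_joint` per (disease, age_band, race_eth)
#' @export
adult_pifs <- function(deltas, pars = default_parameter_library(),
                       rr_tab = expand_rr_library(pars),
                       rr_z = NULL, effect_draw = NULL) {
  missing_f <- setdiff(unique(rr_tab$factor), names(deltas))
  if (length(missing_f)) {
    stop_contract("deltas missing for factor(s): ",
                  paste(missing_f, collapse = ", "))
  }
  ae <- pars$adult_effects
  eff <- list(
    added_sugar_bmi = ae$added_sugar_bmi$point,
    whole_grain_bmi = ae$whole_grain_bmi$point,
    sodium_sbp = ae$sodium_sbp$point
  )
  if (!is.null(effect_draw)) eff[names(effect_draw)] <- effect_draw

  tab <- rr_tab
  z <- if (is.null(rr_z)) rep(0, nrow(tab)) else {
    zz <- rr_z[tab$rr_key]
    zz[is.na(zz)] <- 0
    zz
  }
  tab$log_rr <- tab$age_mult * (log(tab$rr_base) + z * tab$log_se)

  races <- RACE_ETH
  race_mult <- unlist(ae$sodium_sbp$modifiers$race_multiplier)[races]
  hyp <- dplyr::bind_rows(lapply(ae$sodium_sbp$modifiers$hypertension, tibble::as_tibble))
  wtst <- dplyr::bind_rows(lapply(pars$rr_library$bmi_mediated$weight_status,
                                  tibble::as_tibble))

  rr_mult_for <- function(p) {
    d <- deltas[p$factor]
    if (p$path[1] == "direct") {
      matrix(exp(p$log_rr / p$per * d), nrow = nrow(p), ncol = length(races))
    } else if (p$path[1] == "bmi_mediated") {
      effv <- unlist(eff)[paste0(p$factor, "_bmi")]
      dm <- d * effv
      v <- Reduce(`+`, lapply(seq_len(nrow(wtst)), function(i) {
        wtst$prevalence[i] * exp(p$log_rr * wtst$multiplier[i] / p$per * dm)
      }))
      matrix(v, nrow = nrow(p), ncol = length(races))
    } else if (p$path[1] == "sbp_mediated") {
      # delta_SBP = delta_sodium / per_effect * effect, by hypertension and race
      base_dm <- d / ae$sodium_sbp$per * eff$sodium_sbp
      m <- vapply(seq_along(races), function(r) {
        Reduce(`+`, lapply(seq_len(nrow(hyp)), function(i) {
          hyp$prevalence[i] *
            exp(p$log_rr / p$per * base_dm * hyp$multiplier[i] * race_mult[r])
        }))
      }, numeric(nrow(p)))
      matrix(m, nrow = nrow(p), ncol = length(races))
    } else {
      stop_contract("unknown RR path: ", p$path[1])
    }
  }

  parts <- tab |>
    dplyr::group_by(.data$path) |>
    dplyr::group_split()
  long <- purrr::map_dfr(parts, function(p) {
    m <- rr_mult_for(p)
    # one column per race
    tidyr::crossing(i = seq_len(nrow(p)), race_eth = races) |>
      dplyr::mutate(factor = p$factor[.data$i], disease = p$disease[.data$i],
                    age_band = p$age_band[.data$i], path = p$path[1],
                    rr_mult = as.numeric(m[cbind(.data$i, match(.data$race_eth, races))])) |>
      dplyr::select(-"i")
  })

  per_factor <- long |>
    dplyr::group_by(.data$disease, .data$age_band, .data$race_eth, .data$factor) |>
    dplyr::summarise(rr_total = prod(.data$rr_mult), .groups = "drop") |>
    dplyr::mutate(pif = pif_for_factor(.data$rr_total))

  joint <- per_factor |>
    dplyr::group_by(.data$disease, .data$age_band, .data$race_eth) |>
    dplyr::summarise(pif_joint = 1 - prod(1 - .data$pif), .groups = "drop")

  dplyr::left_join(per_factor, joint,
                   by = c("disease", "age_band", "race_eth"))
}

#' Attribute deaths, DALYs, and costs to the dietary change
#'
#' Deaths prevented are `sum over strata of PIF(stratum, disease) x deaths`;
#' DALYs use age-by-sex strata with the race-collapsed, death-weighted mean
#' PIF (DALY sources carry no race dimension); cost savings apply the
#' death-weighted mean PIF of each disease group to the national direct and
#' indirect cost totals separately.
#'
#' @param pifs table from [adult_pifs()]
#' @param rates mortality table (`generate_adult_inputs()$rates`)
#' @param dalys DALY table by age band, sex, disease
#' @param costs cost table by disease group
#' @param pif_column which PIF to attribute (`"pif_joint"` for the combined
#'   standards, `"pif"` with `factor_filter` for one factor)
#' @param factor_filter restrict to one dietary factor (with `pif_column = "pif"`)
#' @return list: `by_group` tibble (disease_group, deaths_prevented,
#'   dalys_prevented, cost PIF, direct/indirect/total savings $B) and
#'   `total` one-row tibble
#' @export
attribute_burden <- function(pifs, rates, dalys, costs,
                             pif_column = "pif_joint", factor_filter = NULL) {
  p <- pifs
  if (!is.null(factor_filter)) p <- p[p$factor == factor_filter, ]
  p <- dplyr::distinct(p, .data$disease, .data$age_band, .data$race_eth,
                       .keep_all = TRUE)
  p$`.pif` <- p[[pif_column]]

  # diseases untouched by any RR path carry PIF 0; but a disease present in
  # the PIF table must cover every (age, race) cell of the rate table
  joined <- dplyr::left_join(rates, p[, c("disease", "age_band", "race_eth", ".pif")],
                             by = c("disease", "age_band", "race_eth"))
  covered <- joined$disease %in% unique(p$disease)
  if (any(covered & is.na(joined$`.pif`))) {
    stop_schema("attribute_burden: PIF table does not cover all rate strata")
  }
  joined$`.pif`[is.na(joined$`.pif`)] <- 0
  joined$prevented <- joined$`.pif` * joined$deaths_per_year

  by_disease <- joined |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(deaths = sum(.data$deaths_per_year),
                     prevented = sum(.data$prevented), .groups = "drop")

  # race-collapsed PIF per (disease, age, sex), weighted by deaths
  pif_age_sex <- joined |>
    dplyr::group_by(.data$disease, .data$age_band, .data$sex) |>
    dplyr::summarise(
      pif = sum(.data$`.pif` * .data$deaths_per_year) /
        pmax(sum(.data$deaths_per_year), 1e-12),
      .groups = "drop")
  daly_prev <- dplyr::inner_join(dalys, pif_age_sex,
                                 by = c("disease", "age_band", "sex")) |>
    dplyr::mutate(prevented = .data$pif * .data$dalys_per_year)

  grp <- by_disease |>
    dplyr::mutate(disease_group = disease_group(.data$disease)) |>
    dplyr::group_by(.data$disease_group) |>
    dplyr::summarise(deaths = sum(.data$deaths),
                     deaths_prevented = sum(.data$prevented), .groups = "drop") |>
    dplyr::mutate(cost_pif = .data$deaths_prevented / .data$deaths)
  daly_grp <- daly_prev |>
    dplyr::mutate(disease_group = disease_group(.data$disease)) |>
    dplyr::group_by(.data$disease_group) |>
    dplyr::summarise(dalys_prevented = sum(.data$prevented), .groups = "drop")

  by_group <- grp |>
    dplyr::left_join(daly_grp, by = "disease_group") |>
    dplyr::left_join(costs, by = "disease_group") |>
    dplyr::mutate(
      direct_savings_busd = .data$cost_pif * .data$direct_cost_busd2019,
      indirect_savings_busd = .data$cost_pif * .data$indirect_cost_busd2019,
      total_savings_busd = .data$direct_savings_busd + .data$indirect_savings_busd
    ) |>
    dplyr::select("disease_group", "deaths_prevented", "dalys_prevented",
                  "cost_pif", "direct_savings_busd", "indirect_savings_busd",
                  "total_savings_busd")

  total <- by_group |>
    dplyr::summarise(
      deaths_prevented = sum(.data$deaths_prevented),
      dalys_prevented = sum(.data$dalys_prevented),
      direct_savings_busd = sum(.data$direct_savings_busd),
      indirect_savings_busd = sum(.data$indirect_savings_busd),
      total_savings_busd = sum(.data$total_savings_busd)
    )
  list(by_group = by_group, total = total)
}
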
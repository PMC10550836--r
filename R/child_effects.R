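#' Childhood BMI change from an added-sugar intake change
#'
#' Linear in the dietary delta: `delta * effect_point`, where the effect is
#' expressed per gram of added sugar per day (the per-serving SSB evidence
#' divided by 20.5 g/serving; see [ssb_effect_per_gram()]).  Reported values
#' are rounded to two decimals.
#' @param delta_added_sugar signed change in habitual added sugars, g/d
#' @param effect one-row spec from [child_effect_spec()] with outcome `"BMI"`
#' @return signed BMI change, kg/m2 (full precision; round for reporting)
#' @examples
#' eff <- child_effect_spec(default_parameter_library(), "added_sugar_bmi")
#' round_half_up(bmi_change(-2.72, eff), 2)  # -0.14
#' @export
bmi_change <- function(delta_added_sugar, effect) {
  if (!identical(effect$outcome, "BMI")) {
    stop_contract("bmi_change requires a BMI effect spec")
  }
  delta_added_sugar / effect$per * effect$point
}

#' Childhood blood-pressure change from a sodium intake change
#'
#' `(delta / 1000) * effect_point`, with the effect expressed per 1000 mg/d
#' of sodium.  Applies to systolic or diastolic pressure depending on the
#' spec's outcome.
#' @param delta_sodium signed change in habitual sodium, mg/d
#' @param effect one-row spec with outcome `"SBP"` or `"DBP"`
#' @return signed BP change, mm Hg
#' @examples
#' eff <- child_effect_spec(default_parameter_library(), "sodium_sbp")
#' round_half_up(bp_change(-165, eff), 2)  # -0.13
#' @export
bp_change <- function(delta_sodium, effect) {
  if (!effect$outcome %in% c("SBP", "DBP")) {
    stop_contract("bp_change requires an SBP or DBP effect spec")
  }
  delta_sodium / effect$per * effect$point
}

#' Childhood outcome changes by grade band
#'
#' Maps habitual intake changes to childhood risk-factor changes: BMI
#' responds to added sugars only, systolic and diastolic BP to sodium only,
#' and whole grains contribute nothing (no effect modelled, reflecting the
#' inconclusive evidence for childhood whole-grain effects on BMI/BP).
#' Uncertainty intervals combine the intake-change SE with the effect-size
#' CI by Monte Carlo (both sampled as normals; see [draw_parameters()]).
#'
#' @param changes intake-change table from [habitual_change()] (one scenario)
#' @param pars parameter library
#' @param n_draws Monte Carlo draws for the 95% UI (0 = point estimates only)
#' @param seed seed for the UI draws
#' @return tibble: grade_band, outcome, delta_point, ui_low, ui_high
#' @export
child_outcomes <- function(changes, pars = default_parameter_library(),
                           n_draws = 1000, seed = 1) {
  needed <- tidyr::crossing(grade_band = unique(changes$grade_band),
                            factor = c("added_sugar", "sodium"))
  have <- dplyr::distinct(changes, .data$grade_band, .data$factor)
  gaps <- dplyr::anti_join(needed, have, by = c("grade_band", "factor"))
  if (nrow(gaps)) {
    stop_contract("child_outcomes: missing factors for grade band(s): ",
                  paste(unique(gaps$grade_band), collapse = ", "))
  }
  specs <- list(
    BMI = child_effect_spec(pars, "added_sugar_bmi"),
    SBP = child_effect_spec(pars, "sodium_sbp"),
    DBP = child_effect_spec(pars, "sodium_dbp")
  )
  purrr::map_dfr(names(specs), function(outc) {
    spec <- specs[[outc]]
    ch <- changes[changes$factor == spec$factor, ]
    purrr::map_dfr(seq_len(nrow(ch)), function(i) {
      point <- ch$delta_mean[i] / spec$per * spec$point
      if (n_draws > 0) {
        withr::local_seed(as.integer(seed))
        d_delta <- stats::rnorm(n_draws, ch$delta_mean[i], ch$se_delta[i])
        d_eff <- stats::rnorm(n_draws, spec$point, spec$se)
        draws <- d_delta / spec$per * d_eff
        ui <- summarize_ui(draws)
        lo <- ui$p2.5; hi <- ui$p97.5
      } else {
        lo <- point; hi <- point
      }
      tibble::tibble(grade_band = ch$grade_band[i], outcome = outc,
                     delta_point = point, ui_low = lo, ui_high = hi)
    })
  })
}
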
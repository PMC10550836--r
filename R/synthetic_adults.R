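#' Simulate adult intake strata, mortality/DALY rates, and cost tables
#'
#' Builds the three adult-side inputs of the CRA:
#' * 48 intake strata (6 age bands x 2 sexes x 4 race/ethnicity groups) with
#'   mean daily intake of each dietary factor and a population count;
#' * a mortality table with annual deaths per (stratum, disease) for CHD,
#'   stroke, diabetes and 15 cancer-site streams, plus a DALY table by
#'   age x sex only (DALY sources carry no race/ethnicity dimension);
#' * the national annual cost table (direct medical and indirect/productivity
#'   costs in $B 2019) per disease group.
#'
#' Mortality magnitudes are order-of-magnitude realistic but synthetic
#' (deterministic age/sex/race shares times a seeded lognormal jitter); no
#' downstream conclusion depends on their exact values.  Cost totals are the
#' published national figures from the parameter library.
#'
#' @param seed integer seed for the stratum-level jitter
#' @param pars parameter library; `generator$adult` and `costs_busd2019`
#'   sections are used
#' @return list with tibbles `intakes` (age_band, sex, race_eth, factor,
#'   mean_intake, population_count), `rates` (stratum x disease deaths),
#'   `dalys` (age_band, sex, disease, dalys_per_year), `costs`
#' @examples
#' adult <- generate_adult_inputs(seed = 1)
#' nrow(dplyr::distinct(adult$intakes, age_band, sex, race_eth))  # 48
#' @export
generate_adult_inputs <- function(seed = 1, pars = default_parameter_library()) {
  cfg <- pars$generator$adult
  need <- c("population_millions", "race_probs", "intake_mean", "deaths_total",
            "age_death_shares", "daly_per_death")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop_schema("adult generator config missing: ", paste(missing, collapse = ", "))
  }
  if (!setequal(names(cfg$population_millions), AGE_BANDS)) {
    stop_schema("adult config must cover all age bands: ",
                paste(AGE_BANDS, collapse = ", "))
  }
  withr::local_seed(as.integer(seed))

  strata <- tidyr::crossing(age_band = AGE_BANDS, sex = SEXES,
                            race_eth = names(cfg$race_probs)) |>
    dplyr::mutate(
      race_share = unlist(cfg$race_probs)[.data$race_eth],
      population_count = unlist(cfg$population_millions)[.data$age_band] * 1e6 *
        0.5 * .data$race_share
    ) |>
    dplyr::select(-"race_share")

  age_idx <- stats::setNames(seq_along(AGE_BANDS), AGE_BANDS)
  intakes <- tidyr::crossing(strata, factor = DIET_FACTORS) |>
    dplyr::mutate(
      mean_intake = purrr::map2_dbl(.data$factor, .data$age_band, function(f, a) {
        spec <- cfg$intake_mean[[f]]
        max(spec$base + spec$age_slope * (age_idx[[a]] - 1), 0)
      })
    )

  diseases <- names(cfg$deaths_total)
  age_share <- stats::setNames(unlist(cfg$age_death_shares), AGE_BANDS)
  male_share <- cfg$male_share
  rates <- tidyr::crossing(strata, disease = diseases) |>
    dplyr::mutate(
      sex_share = dplyr::case_when(
        .data$disease %in% unlist(cfg$female_only) & .data$sex == "male" ~ 0,
        .data$disease %in% unlist(cfg$female_only) ~ 1,
        .data$disease %in% unlist(cfg$male_only) & .data$sex == "female" ~ 0,
        .data$disease %in% unlist(cfg$male_only) ~ 1,
        .data$sex == "male" ~ male_share,
        TRUE ~ 1 - male_share
      ),
      deaths_per_year = unlist(cfg$deaths_total)[.data$disease] *
        age_share[.data$age_band] * .data$sex_share *
        unlist(cfg$race_probs)[.data$race_eth] *
        stats::rlnorm(dplyr::n(), -cfg$death_jitter_log_sd^2 / 2,
                      cfg$death_jitter_log_sd)
    ) |>
    dplyr::select(-"sex_share")

  daly_ratio <- function(d) {
    g <- disease_group(d)
    key <- if (g == "cancer") "cancer" else if (g == "diabetes") "diabetes" else d
    r <- cfg$daly_per_death[[key]]
    if (is.null(r)) cfg$daly_per_death[["cancer"]] else r
  }
  dalys <- rates |>
    dplyr::group_by(.data$age_band, .data$sex, .data$disease) |>
    dplyr::summarise(deaths = sum(.data$deaths_per_year), .groups = "drop") |>
    dplyr::mutate(dalys_per_year = .data$deaths *
                    purrr::map_dbl(.data$disease, daly_ratio)) |>
    dplyr::select("age_band", "sex", "disease", "dalys_per_year")

  costs <- purrr::imap_dfr(pars$costs_busd2019, ~ tibble::tibble(
    disease_group = .y,
    direct_cost_busd2019 = .x$direct,
    indirect_cost_busd2019 = .x$indirect
  ))

  list(intakes = intakes, rates = rates, dalys = dalys, costs = costs)
}
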
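#' Precompiled PIF engine
#'
#' Builds a closure that evaluates per-stratum PIFs as pure vector
#' arithmetic over a precomputed (RR row x race) grid, for repeated calls
#' inside the Monte Carlo loop.  Produces exactly the quantities of
#' [adult_pifs()] (verified against it in the test suite); only the
#' evaluation strategy differs.
#'
#' @param pars parameter library
#' @return function(deltas, rr_z, effect_draw) returning a list with
#'   `cells` (disease, age_band, race_eth), `pif_joint`, and `pif_factor`
#'   (matrix cells x factors)
#' @keywords internal
build_pif_engine <- function(pars) {
  rr_tab <- expand_rr_library(pars)
  races <- RACE_ETH
  ae <- pars$adult_effects
  wtst <- dplyr::bind_rows(lapply(pars$rr_library$bmi_mediated$weight_status,
                                  tibble::as_tibble))
  hyp <- dplyr::bind_rows(lapply(ae$sodium_sbp$modifiers$hypertension,
                                 tibble::as_tibble))
  race_mult <- unlist(ae$sodium_sbp$modifiers$race_multiplier)[races]

  grid <- tidyr::crossing(rr_tab, race_eth = races)
  rr_keys <- unique(rr_tab$rr_key)
  g <- list(
    path = grid$path,
    per = grid$per,
    age_mult = grid$age_mult,
    log_rr_base = log(grid$rr_base),
    log_se = grid$log_se,
    z_idx = match(grid$rr_key, rr_keys),
    delta_idx = match(grid$factor, DIET_FACTORS),
    race_mult = race_mult[grid$race_eth],
    eff_name = dplyr::case_when(
      grid$path == "bmi_mediated" ~ paste0(grid$factor, "_bmi"),
      grid$path == "sbp_mediated" ~ "sodium_sbp",
      TRUE ~ NA_character_)
  )
  cells <- dplyr::distinct(grid, .data$disease, .data$age_band, .data$race_eth)
  cell_id <- match(paste(grid$disease, grid$age_band, grid$race_eth),
                   paste(cells$disease, cells$age_band, cells$race_eth))
  n_cells <- nrow(cells)
  factor_id <- match(grid$factor, DIET_FACTORS)
  is_direct <- g$path == "direct"
  is_bmi <- g$path == "bmi_mediated"
  is_sbp <- g$path == "sbp_mediated"

  point_effects <- c(added_sugar_bmi = ae$added_sugar_bmi$point,
                     whole_grain_bmi = ae$whole_grain_bmi$point,
                     sodium_sbp = ae$sodium_sbp$point)
  sbp_per_eff <- ae$sodium_sbp$per

  function(deltas, rr_z = NULL, effect_draw = NULL) {
    eff <- point_effects
    if (!is.null(effect_draw)) eff[names(effect_draw)] <- unlist(effect_draw)
    z <- if (is.null(rr_z)) numeric(length(rr_keys)) else {
      zz <- rr_z[rr_keys]
      zz[is.na(zz)] <- 0
      zz
    }
    log_rr <- g$age_mult * (g$log_rr_base + z[g$z_idx] * g$log_se)
    d <- unname(deltas[DIET_FACTORS])[g$delta_idx]

    lm <- numeric(length(log_rr))
    lm[is_direct] <- (log_rr / g$per * d)[is_direct]
    if (any(is_bmi)) {
      dm <- (d * eff[g$eff_name])[is_bmi]
      lrr <- log_rr[is_bmi] / g$per[is_bmi]
      lm[is_bmi] <- log(Reduce(`+`, lapply(seq_len(nrow(wtst)), function(i) {
        wtst$prevalence[i] * exp(lrr * wtst$multiplier[i] * dm)
      })))
    }
    if (any(is_sbp)) {
      dm <- (d / sbp_per_eff * eff["sodium_sbp"] * g$race_mult)[is_sbp]
      lrr <- log_rr[is_sbp] / g$per[is_sbp]
      lm[is_sbp] <- log(Reduce(`+`, lapply(seq_len(nrow(hyp)), function(i) {
        hyp$prevalence[i] * exp(lrr * dm * hyp$multiplier[i])
      })))
    }

    joint_sum <- numeric(n_cells)
    fac_sum <- matrix(0, n_cells, length(DIET_FACTORS))
    agg <- rowsum(lm, cell_id)
    joint_sum[as.integer(rownames(agg))] <- agg[, 1]
    for (fi in seq_along(DIET_FACTORS)) {
      sel <- factor_id == fi
      if (any(sel)) {
        a <- rowsum(lm[sel], cell_id[sel])
        fac_sum[as.integer(rownames(a)), fi] <- a[, 1]
      }
    }
    list(cells = cells, pif_joint = 1 - exp(joint_sum),
         pif_factor = 1 - exp(fac_sum))
  }
}

#' Precompiled burden attribution
#'
#' Precomputes the integer joins between the PIF cell grid, the mortality
#' table, the DALY table, and the cost table, returning a closure that
#' attributes deaths, DALYs, and costs from a PIF evaluation and the draw's
#' rate/DALY/cost scalers.  Mirrors [attribute_burden()] (verified against
#' it in the test suite).
#' @param cells cell grid from the PIF engine
#' @param adult list from [generate_adult_inputs()]
#' @keywords internal
build_attribution_engine <- function(cells, adult) {
  rates <- adult$rates
  dalys <- adult$dalys
  costs <- adult$costs
  groups <- costs$disease_group

  cell_of_rate <- match(paste(rates$disease, rates$age_band, rates$race_eth),
                        paste(cells$disease, cells$age_band, cells$race_eth))
  grp_rate <- match(disease_group(rates$disease), groups)
  as_key <- paste(rates$disease, rates$age_band, rates$sex)
  as_levels <- unique(as_key)
  as_idx <- match(as_key, as_levels)
  daly_idx <- match(paste(dalys$disease, dalys$age_band, dalys$sex), as_levels)
  grp_daly <- match(disease_group(dalys$disease), groups)
  deaths0 <- rates$deaths_per_year
  dalys0 <- dalys$dalys_per_year

  group_sums <- function(x, idx) {
    out <- numeric(length(groups))
    a <- rowsum(x, idx)
    out[as.integer(rownames(a))] <- a[, 1]
    out
  }

  function(pif_cells, rate_scaler = NULL, daly_scaler = NULL,
           cost_scaler = NULL) {
    pif <- c(pif_cells, 0)[ifelse(is.na(cell_of_rate),
                                  length(pif_cells) + 1L, cell_of_rate)]
    deaths <- if (is.null(rate_scaler)) deaths0 else
      deaths0 * rate_scaler[groups][grp_rate]
    prevented <- pif * deaths
    deaths_g <- group_sums(deaths, grp_rate)
    prevented_g <- group_sums(prevented, grp_rate)

    prev_as <- rowsum(prevented, as_idx)
    dth_as <- rowsum(deaths, as_idx)
    pif_as <- numeric(length(as_levels))
    pif_as[as.integer(rownames(prev_as))] <-
      prev_as[, 1] / pmax(dth_as[, 1], 1e-12)
    dl <- if (is.null(daly_scaler)) dalys0 else
      dalys0 * daly_scaler[groups][grp_daly]
    dalys_prev_g <- group_sums(pif_as[daly_idx] * dl, grp_daly)

    cost_pif <- prevented_g / pmax(deaths_g, 1e-12)
    cmul <- if (is.null(cost_scaler)) rep(1, length(groups)) else
      cost_scaler[groups]
    direct <- cost_pif * costs$direct_cost_busd2019 * cmul
    indirect <- cost_pif * costs$indirect_cost_busd2019 * cmul

    list(groups = groups, deaths_prevented = prevented_g,
         dalys_prevented = dalys_prev_g, cost_pif = cost_pif,
         direct = direct, indirect = indirect, total = direct + indirect)
  }
}
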
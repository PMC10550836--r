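#' Build the adult burden evaluator
#'
#' Precomputes everything static (expanded RR table, adult rate/DALY/cost
#' tables, grade population shares) and returns a pure function of one
#' parameter draw that runs child-change persistence, the PIF engine, and
#' burden attribution, returning a named vector of reported quantities
#' (`deaths_<group>`, `dalys_<group>`, `direct_<group>`, `indirect_<group>`,
#' `total_<group>`, the corresponding `_total`s and, optionally,
#' `deaths_factor_<factor>` from single-factor PIFs).
#'
#' @param changes intake-change table (one scenario, grade-band strata)
#' @param adult list from [generate_adult_inputs()]
#' @param pars parameter library
#' @param kappa persistence fraction
#' @param grade_weights named grade population shares
#' @param include_factors also attribute per-factor burdens (slower)
#' @return function(draw) -> named numeric; call with `draw = NULL` for the
#'   deterministic point run
#' @export
burden_evaluator <- function(changes, adult, pars = default_parameter_library(),
                             kappa = pars$persistence$point,
                             grade_weights = NULL, include_factors = FALSE) {
  pif_engine <- build_pif_engine(pars)
  cells <- pif_engine(stats::setNames(rep(0, 3), DIET_FACTORS))$cells
  attribute <- build_attribution_engine(cells, adult)
  key0 <- paste(changes$grade_band, changes$factor)

  function(draw = NULL) {
    ch <- changes
    if (!is.null(draw)) {
      ch$delta_mean <- draw$child_deltas$delta[
        match(key0, paste(draw$child_deltas$grade_band, draw$child_deltas$factor))]
    }
    deltas <- persist_change(ch, kappa, grade_weights)
    p <- pif_engine(deltas,
                    rr_z = if (is.null(draw)) NULL else draw$rr_z,
                    effect_draw = if (is.null(draw)) NULL else draw$adult_effects)
    sc <- if (is.null(draw)) list(rate = NULL, daly = NULL, cost = NULL) else
      draw$scalers
    b <- attribute(p$pif_joint, sc$rate, sc$daly, sc$cost)
    out <- c(
      stats::setNames(b$deaths_prevented, paste0("deaths_", b$groups)),
      stats::setNames(b$dalys_prevented, paste0("dalys_", b$groups)),
      stats::setNames(b$cost_pif, paste0("pif_", b$groups)),
      stats::setNames(b$direct, paste0("direct_", b$groups)),
      stats::setNames(b$indirect, paste0("indirect_", b$groups)),
      stats::setNames(b$total, paste0("totalcost_", b$groups)),
      deaths_total = sum(b$deaths_prevented),
      dalys_total = sum(b$dalys_prevented),
      direct_total = sum(b$direct),
      indirect_total = sum(b$indirect),
      totalcost_total = sum(b$total)
    )
    if (include_factors) {
      for (fi in seq_along(DIET_FACTORS)) {
        bf <- attribute(p$pif_factor[, fi], sc$rate, sc$daly, sc$cost)
        out[paste0("deaths_factor_", DIET_FACTORS[fi])] <- sum(bf$deaths_prevented)
        out[paste0("totalcost_factor_", DIET_FACTORS[fi])] <- sum(bf$total)
      }
    }
    out
  }
}

#' Run the full comparative risk assessment pipeline
#'
#' Chains every stage: synthetic child population -> DGA-aligned standards
#' -> habitual intake changes (full and partial compliance) -> childhood
#' BMI/BP outcomes -> persistence into adulthood -> PIF engine -> burden
#' attribution -> Monte Carlo uncertainty.  Re-running an identical config
#' reproduces every output bit for bit.
#'
#' @param config list with any of: `n_children` (default 4000), `seed` (1),
#'   `scenario` (`"full"`), `kappa` (library default 0.35), `n_draws` (1000),
#'   `out_dir` (optional: write tables + run log there),
#'   `baseline_source` (`"microdata"` or `"external-means"`: percent changes
#'   against configured external habitual means instead of the microdata),
#'   `include_factors` (FALSE), `pars` (parameter library or YAML path)
#' @return list: `standards`, `changes` (both scenarios), `child_outcomes`,
#'   `burden_point` (named vector), `burden` (tidy table with medians and
#'   95% UIs), `meta` (seed, config hash, version)
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_children = 4000, seed = 1, scenario = "full", n_draws = 1000,
    out_dir = NULL, baseline_source = "microdata", include_factors = FALSE
  ), config)
  pars <- cfg$pars
  if (is.null(pars)) pars <- default_parameter_library()
  if (is.character(pars)) pars <- default_parameter_library(pars)
  if (is.null(cfg$kappa)) cfg$kappa <- pars$persistence$point
  if (!cfg$scenario %in% c("full", "partial")) {
    stop_parameter("scenario must be 'full' or 'partial'")
  }
  if (cfg$kappa < 0 || cfg$kappa > 1) stop_parameter("kappa must lie in [0, 1]")
  seed <- as.integer(cfg$seed)

  kids <- generate_child_population(cfg$n_children, seed = seed, pars = pars)
  standards <- build_standards(pars)
  compliance <- build_compliance_model(pars)

  changes <- dplyr::bind_rows(
    habitual_change(kids, standards, compliance, "full"),
    habitual_change(kids, standards, compliance, "partial")
  )
  if (cfg$baseline_source == "external-means") {
    ext <- pars$generator$child$habitual_targets
    changes <- changes |>
      dplyr::mutate(
        baseline_mean = purrr::map2_dbl(.data$factor, .data$grade_band,
                                        ~ ext[[.x]][[.y]]),
        percent_change = percent_change(.data$delta_mean, .data$baseline_mean))
  }
  ch_scen <- changes[changes$scenario == cfg$scenario, ]

  child_out <- child_outcomes(ch_scen, pars, n_draws = cfg$n_draws,
                              seed = seed + 1L)

  adult <- generate_adult_inputs(seed = seed + 2L, pars = pars)
  gw <- grade_population_shares(kids)
  evaluate <- burden_evaluator(ch_scen, adult, pars, kappa = cfg$kappa,
                               grade_weights = gw,
                               include_factors = isTRUE(cfg$include_factors))
  point <- evaluate(NULL)

  burden <- NULL
  if (cfg$n_draws >= 2) {
    draws <- draw_parameters(pars, ch_scen, n_draws = cfg$n_draws,
                             seed = seed + 3L)
    mc <- run_monte_carlo(evaluate, draws)
    burden <- mc |>
      dplyr::group_by(.data$name) |>
      dplyr::group_modify(~ summarize_ui(.x$value)) |>
      dplyr::ungroup() |>
      dplyr::rename(quantity = "name", ui_low = "p2.5", ui_high = "p97.5") |>
      dplyr::mutate(point = point[.data$quantity],
                    scenario = cfg$scenario, kappa = cfg$kappa) |>
      dplyr::select("scenario", "kappa", "quantity", "point", "median",
                    "ui_low", "ui_high", "n_draws")
  }

  meta <- list(
    seed = seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
    version = as.character(utils::packageVersion("schoolmealcra")),
    scenario = cfg$scenario, kappa = cfg$kappa, n_children = cfg$n_children,
    n_draws = cfg$n_draws
  )
  out <- list(standards = standards, changes = changes,
              child_outcomes = child_out, burden_point = point,
              burden = burden, meta = meta)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- meta[c("seed", "config_hash", "version")]
    write_table(standards, file.path(cfg$out_dir, "standards.csv"), hdr)
    write_table(changes, file.path(cfg$out_dir, "intake_changes.csv"), hdr)
    write_table(child_out, file.path(cfg$out_dir, "child_outcomes.csv"), hdr)
    if (!is.null(burden)) {
      write_table(burden, file.path(cfg$out_dir, "adult_burden.csv"), hdr)
    }
    yaml::write_yaml(meta, file.path(cfg$out_dir, "run_log.yaml"))
  }
  out
}
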
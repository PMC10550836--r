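#' Sample parameter draws for Monte Carlo uncertainty propagation
#'
#' One draw jointly samples every uncertain model input:
#' * stratum intake deltas -- normal around the estimated change with its SE;
#' * child effect sizes (added sugar to BMI, sodium to SBP/DBP) -- normal
#'   with SE = CI width / 3.92;
#' * adult mediator effects -- normal around their points;
#' * every relative risk -- normal on the log scale (a standard-normal
#'   perturbation `z` per RR spec, applied as `log RR + z * log_se`);
#' * mortality, DALY, and cost scalers -- lognormal with mean 1 per disease
#'   group.
#' All parameters are drawn independently; draws are reproducible from the
#' seed.  Setting every SE / spread to zero makes each draw equal the point
#' estimates.
#'
#' @param pars parameter library
#' @param changes intake-change table whose `delta_mean`/`se_delta` are
#'   sampled (`NULL` to skip)
#' @param n_draws number of draws (>= 1); the reported analyses use 1000
#' @param seed integer seed
#' @return list of draws; each draw is a list with elements `child_deltas`,
#'   `child_effects`, `adult_effects`, `rr_z`, `scalers`
#' @export
draw_parameters <- function(pars, changes = NULL, n_draws = 1000, seed = 1) {
  if (!is.numeric(n_draws) || n_draws < 1) {
    stop_parameter("n_draws must be a count >= 1")
  }
  n_draws <- as.integer(n_draws)
  withr::local_seed(as.integer(seed))

  ce <- lapply(c(added_sugar_bmi = "added_sugar_bmi", sodium_sbp = "sodium_sbp",
                 sodium_dbp = "sodium_dbp"),
               function(nm) child_effect_spec(pars, nm))
  ae <- pars$adult_effects
  rr_keys <- unique(expand_rr_library(pars)$rr_key)
  u <- pars$uncertainty
  groups <- names(pars$costs_busd2019)

  lapply(seq_len(n_draws), function(i) {
    child_deltas <- NULL
    if (!is.null(changes)) {
      child_deltas <- changes |>
        dplyr::mutate(delta = stats::rnorm(dplyr::n(), .data$delta_mean,
                                           .data$se_delta)) |>
        dplyr::select(dplyr::any_of(c("grade_band", "race_eth")),
                      "factor", "scenario", "delta")
    }
    list(
      draw = i,
      child_deltas = child_deltas,
      child_effects = lapply(ce, function(s) stats::rnorm(1, s$point, s$se)),
      adult_effects = list(
        added_sugar_bmi = stats::rnorm(1, ae$added_sugar_bmi$point,
                                       ae$added_sugar_bmi$log_like_se),
        whole_grain_bmi = stats::rnorm(1, ae$whole_grain_bmi$point,
                                       ae$whole_grain_bmi$log_like_se),
        sodium_sbp = stats::rnorm(1, ae$sodium_sbp$point,
                                  ae$sodium_sbp$log_like_se)
      ),
      rr_z = stats::setNames(stats::rnorm(length(rr_keys)), rr_keys),
      scalers = list(
        rate = stats::setNames(
          stats::rlnorm(length(groups), -u$rate_log_sd^2 / 2, u$rate_log_sd), groups),
        daly = stats::setNames(
          stats::rlnorm(length(groups), -u$daly_log_sd^2 / 2, u$daly_log_sd), groups),
        cost = stats::setNames(
          stats::rlnorm(length(groups), -u$cost_log_sd^2 / 2, u$cost_log_sd), groups)
      )
    )
  })
}

#' Run a pipeline evaluator over Monte Carlo draws
#'
#' Applies a pure evaluator (draw -> named numeric vector of reported
#' quantities) to every draw.  A failure on any draw is re-raised with the
#' draw index attached.
#' @param evaluator function taking one draw
#' @param draws list from [draw_parameters()]
#' @return tibble: draw, name, value
#' @export
run_monte_carlo <- function(evaluator, draws) {
  purrr::map_dfr(seq_along(draws), function(i) {
    v <- tryCatch(evaluator(draws[[i]]), error = function(e) {
      rlang::abort(paste0("Monte Carlo evaluator failed on draw ", i, ": ",
                          conditionMessage(e)), parent = e)
    })
    tibble::tibble(draw = i, name = names(v), value = as.numeric(v))
  })
}

#' Median and 95% uncertainty interval of Monte Carlo outputs
#'
#' Empirical median and 2.5th/97.5th percentiles, with linear interpolation
#' between closest ranks (`stats::quantile` type 7), fixed for
#' reproducibility.
#' @param values numeric vector of per-draw values (length >= 2)
#' @return tibble: median, p2.5, p97.5, n_draws
#' @examples
#' summarize_ui(1:1000)  # median 500.5
#' @export
summarize_ui <- function(values) {
  if (length(values) < 2) stop_contract("summarize_ui needs at least 2 values")
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), type = 7, names = FALSE)
  tibble::tibble(median = q[2], p2.5 = q[1], p97.5 = q[3],
                 n_draws = length(values))
}
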
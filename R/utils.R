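#' @keywords internal
"_PACKAGE"

## Shared vocabularies ------------------------------------------------------

GRADE_BANDS <- c("K5", "68", "912")
MEALS <- c("breakfast", "lunch")
DIET_FACTORS <- c("added_sugar", "sodium", "whole_grain")
SEXES <- c("female", "male")
RACE_ETH <- c("NH-White", "NH-Black", "Hispanic", "Other")
AGE_BANDS <- c("25-34", "35-44", "45-54", "55-64", "65-74", "75+")

#' Age range covered by a school grade band
#'
#' K5 covers ages 5-10, 68 ages 11-13, 912 ages 14-18.
#' @param grade_band one of `"K5"`, `"68"`, `"912"`
#' @return integer vector `c(min_age, max_age)`
#' @keywords internal
grade_age_range <- function(grade_band) {
  switch(grade_band,
    K5 = c(5L, 10L),
    `68` = c(11L, 13L),
    `912` = c(14L, 18L),
    stop_parameter("unknown grade_band: ", grade_band)
  )
}

#' Grade band for an age in years
#' @keywords internal
grade_band_for_age <- function(age_y) {
  dplyr::case_when(
    age_y <= 10 ~ "K5",
    age_y <= 13 ~ "68",
    TRUE ~ "912"
  )
}

## Error classes ------------------------------------------------------------

stop_parameter <- function(...) {
  rlang::abort(paste0(...), class = "smc_parameter_error")
}
stop_schema <- function(...) {
  rlang::abort(paste0(...), class = "smc_schema_error")
}
stop_contract <- function(...) {
  rlang::abort(paste0(...), class = "smc_contract_error")
}
stop_estimation <- function(...) {
  rlang::abort(paste0(...), class = "smc_estimation_error")
}

## Numeric helpers ----------------------------------------------------------

#' Round half away from zero
#'
#' Deterministic commercial rounding (0.5 always rounds away from zero),
#' used wherever a reported table value has a fixed number of decimals.
#' Avoids both IEEE representation surprises and banker's rounding.
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so values like 13.75 stored as 13.74999...
  # still round up as their printed decimal form would
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Survey-weighted mean and its standard error
#'
#' SE is the usual weighted-mean SE under independent sampling,
#' `sqrt(sum(w^2 (x - xbar)^2)) / sum(w)`; complex-survey design effects
#' are out of scope.
#' @param x numeric values
#' @param w positive weights
#' @return list with `mean` and `se`
#' @export
weighted_mean_se <- function(x, w) {
  if (length(x) != length(w) || any(w <= 0)) {
    stop_parameter("weights must be positive and match x in length")
  }
  sw <- sum(w)
  m <- sum(w * x) / sw
  se <- sqrt(sum(w^2 * (x - m)^2)) / sw
  list(mean = m, se = se)
}

#' Standard error from a 95% confidence interval
#'
#' Assumes normality: SE = width / (2 * 1.96) = width / 3.92.
#' @param lower,upper CI bounds
#' @return numeric SE
#' @export
se_from_ci <- function(lower, upper) {
  if (any(upper < lower)) stop_parameter("upper CI bound below lower bound")
  (upper - lower) / 3.92
}
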
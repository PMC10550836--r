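test_that("CI-derived sampling SD matches its definition and the draws", {
  expect_equal(se_from_ci(0.02, 0.08), 0.06 / 3.92)
  spec <- child_effect_spec(PARS, "added_sugar_bmi")
  expect_equal(spec$se, (0.08 - 0.02) / 3.92)
  draws <- draw_parameters(PARS, n_draws = 10000, seed = 2)
  eff <- vapply(draws, function(d) d$child_effects$added_sugar_bmi, 0)
  expect_lt(abs(sd(eff) / spec$se - 1), 0.05)
  expect_lt(abs(mean(eff) - spec$point), 3 * spec$se / sqrt(10000))
})

test_that("draws are deterministic under a fixed seed and reject bad counts", {
  a <- draw_parameters(PARS, n_draws = 20, seed = 5)
  b <- draw_parameters(PARS, n_draws = 20, seed = 5)
  expect_identical(a, b)
  expect_error(draw_parameters(PARS, n_draws = 0), class = "smc_parameter_error")
})

test_that("zero-variance parameters collapse every draw to the point estimates", {
  pars0 <- zero_variance_pars()
  changes <- tibble::tibble(grade_band = "K5", factor = "sodium",
                            scenario = "full", delta_mean = -165, se_delta = 0,
                            baseline_mean = 2933, baseline_se = 0,
                            percent_change = -5.6)
  draws <- draw_parameters(pars0, changes, n_draws = 50, seed = 9)
  expect_true(all(vapply(draws, function(d) d$child_deltas$delta, 0) == -165))
  expect_true(all(vapply(draws, function(d) d$child_effects$sodium_sbp, 0) == 0.8))
  expect_true(all(vapply(draws, function(d) d$scalers$rate["CVD"], 0) == 1))
})

test_that("monte carlo runner propagates failures with the draw index", {
  draws <- draw_parameters(PARS, n_draws = 3, seed = 1)
  out <- run_monte_carlo(function(d) c(x = d$child_effects$sodium_sbp), draws)
  expect_equal(nrow(out), 3)
  expect_error(
    run_monte_carlo(function(d) stop("boom"), draws),
    regexp = "draw 1")
})

test_that("UI summaries use fixed interpolated percentiles", {
  expect_equal(summarize_ui(rep(3, 10)),
               tibble::tibble(median = 3, p2.5 = 3, p97.5 = 3, n_draws = 10))
  s <- summarize_ui(1:1000)
  expect_equal(s$median, 500.5)
  set.seed(123)
  z <- rnorm(1e5)
  sz <- summarize_ui(z)
  expect_equal(sz$p2.5, qnorm(0.025), tolerance = 0.02)
  expect_equal(sz$p97.5, qnorm(0.975), tolerance = 0.02)
  expect_error(summarize_ui(1), class = "smc_contract_error")
})

test_that("a linear output of one normal parameter has calibrated coverage", {
  # outcome = delta * effect with fixed delta: analytic normal quantiles
  spec <- child_effect_spec(PARS, "added_sugar_bmi")
  draws <- draw_parameters(PARS, n_draws = 1000, seed = 11)
  out <- vapply(draws, function(d) -2.72 * d$child_effects$added_sugar_bmi, 0)
  s <- summarize_ui(out)
  expect_equal(s$p2.5, -2.72 * qnorm(0.975, spec$point, spec$se),
               tolerance = 0.02)
  expect_equal(s$p97.5, -2.72 * qnorm(0.025, spec$point, spec$se),
               tolerance = 0.02)
})
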
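---
title: "A comparative risk assessment of DGA-aligned school meal standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A comparative risk assessment of DGA-aligned school meal standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`schoolmealcra` implements a comparative risk assessment (CRA) of aligning
US school-meal nutrition standards for added sugars, sodium, and whole
grains with the 2020–2025 Dietary Guidelines for Americans (DGA).  The
causal chain runs:

1. **Standards.** Per-meal limits are derived from grade-band calorie
   allowances (added sugars: 10% of energy at 4 kcal/g) and from the sodium
   Chronic Disease Risk Reduction (CDRR) daily amount multiplied by the
   share of daily calories each meal contributes.  The whole-grain standard
   requires at least half of the grain mass in grain foods to be whole
   grain.
2. **Counterfactual intake.** For each child, school-meal intakes above a
   limit are capped at the limit net of plate waste; whole-grain intake is
   floored at half the consumed grain mass net of waste.  Schools are
   conservatively assumed never to cut sodium or sugars below the target,
   and meals already within a limit are untouched.  Partial compliance
   mixes the counterfactual with the status quo in proportion to empirical
   noncompliance rates.
3. **Habitual change.** Per-child changes are participation-weighted
   (days per calendar year) sums over breakfast and lunch; strata means use
   survey weights.
4. **Childhood outcomes.** BMI responds linearly to added sugars
   (0.05 kg/m² per g/d, converted from per-serving sugar-sweetened-beverage
   trial evidence at 20.5 g of added sugar per 8-oz serving) and systolic /
   diastolic BP to sodium (0.8 / 0.7 mm Hg per 1000 mg/d).  Whole grains
   have no modelled childhood effect, reflecting inconclusive evidence.
5. **Adulthood.** A fraction κ (base case 0.35, sensitivity 0.25/0.50) of
   the population-weighted childhood change persists into every adult age
   band, as if current adults had experienced the policy at school age.
   Log-linear dose–response curves give, per (disease, age band,
   race/ethnicity) cell, a direct relative-risk multiplier
   `exp(β·Δ)` with `β = log(RR)/unit`, and mediated multipliers through BMI
   (added sugars, whole grains) and systolic BP (sodium).  The potential
   impact fraction is `PIF = 1 − RR_total`, combined across factors as the
   joint multiplicative PIF `1 − Π(1 − PIF_f)`.
6. **Burden.** Deaths prevented are `Σ PIF × deaths` over strata; DALYs use
   age×sex strata with a race-collapsed, death-weighted mean PIF (DALY
   sources carry no race dimension); cost savings apply each disease
   group's death-weighted mean PIF to national direct and indirect cost
   totals ($B 2019: CVD 414/337, diabetes 268/147, cancer 220/101).
7. **Uncertainty.** 1000 Monte Carlo draws jointly sample every uncertain
   input; medians and 2.5th/97.5th percentiles form the 95% uncertainty
   intervals.

## Assumptions worth knowing

* **Uniform-shift PIF.** The PIF is evaluated on subgroup mean shifts under
  log-linear RRs, which is exactly the distributional PIF when the whole
  intake distribution shifts by Δ.  `pif_distributional()` retains the
  numerical-integration route as an oracle; it integrates a baseline
  truncated at extreme quantiles because the exponential moment of an
  untruncated lognormal diverges for positive β (the uniform-shift identity
  is unaffected by truncation).
* **No double counting.** Direct cohort RRs are multivariable-adjusted
  including BMI and BP, so direct and mediated multipliers are combined by
  multiplication.
* **Mediation modifiers.** The BMI path blends RRs over weight-status
  strata and the sodium→SBP effect over hypertension strata
  (prevalence-weighted), with a race multiplier on the sodium→SBP effect —
  so sodium PIFs vary by race while other paths are race-invariant.  The
  BP-mediated path applies to both CHD and stroke by default; a
  stroke-only variant is a config flag.
* **Childhood outcomes do not feed the adult model**; adult effects run
  through dietary persistence only.
* **Cancer** is modelled as 15 site-specific mortality streams aggregated
  to one cost group; twelve sites are tagged obesity-related and receive
  the BMI-mediated path.

## Parameters and defaults

All numeric inputs live in `inst/extdata/default_parameters.yaml`; the code
carries no constants.  Calorie allowances (breakfast 500/550/600 kcal,
lunch 650/700/850 kcal), CDRR values (1500/1800/2300 mg), and meal calorie
fractions are chosen to reproduce the published per-meal limits exactly;
the 9–12 lunch added-sugar cell uses a per-cell override (21 g where the
general one-decimal rounding rule would give 21.3 g), reproducing the
printed table verbatim rather than guessing a uniform rounding rule.
Rounding of reported values is half-away-from-zero (`round_half_up()`),
avoiding banker's-rounding surprises.

Noncompliance defaults are 0.20 for added sugars (a stated assumption for a
standard with no compliance history), 0.30 for sodium and 0.09 for whole
grains (mid-range of the empirically reported 24–35% and 4–14% spans), each
overridable per (factor, meal, grade band).  Plate-waste fractions (0.20 /
0.12 / 0.25) are plausible placeholders for survey-derived values that were
never published in detail; waste applies to offered amounts, so consumed
amounts are compared against `limit × (1 − waste)` — equivalent to assuming
current waste persists under the new standard.

Adult relative risks, mediator effects, and mortality magnitudes are
**placeholders**: literature-plausible values tagged `source: placeholder`
in the parameter file, standing in for appendix-calibrated inputs that are
not published.  Every conclusion drawn from the adult model in this package
is therefore structural (orderings, identities, conservation), never a
particular burden number.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* **Intakes** are lognormal (nonnegative, right-skewed) with a
  between-person and a within-person (day-to-day) variance component on the
  log scale (SDs 0.40 and 0.25), two recall days per child.
* **Whole grain** is a Beta-distributed person-level share (school mean
  0.20, other sources 0.15) of lognormal grain mass — so most grain is
  refined at baseline and the whole-grain-rich floor binds.
* **Participation** is a Beta-distributed per-child propensity realised as
  Binomial participation over a 180-day school year, declining from
  elementary (lunch 0.60) to high school (0.35), which is why estimated
  changes are smallest for high-school students.
* **Calibration.** Per-meal means were calibrated once, by simulation
  root-finding, so grade-level habitual means land on the configured
  targets (e.g. elementary added sugars 69.5 g/d, sodium 2933 mg/d, whole
  grains 26.0 g/d) and the full-compliance sodium change lands near the
  configured −165 mg/d at the elementary level.  The calibrated means are
  frozen in the parameter file and are not tuning knobs.
* **Adult tables** cover the full 48-stratum crossing (6 age bands × 2
  sexes × 4 race/ethnicity groups) with order-of-magnitude-realistic but
  synthetic mortality; DALYs are age×sex only; sex-specific cancers carry
  zero deaths in the other sex.

What it does **not** emulate: NHANES complex survey design (weights are a
mild lognormal with mean 1; design effects are ignored), à-la-carte
purchases (all school-cafeteria intake is treated as school-meal intake,
which likely overstates the regulated share), item-level food detail,
multi-day correlation beyond the single between/within split, and secular
trends.  Passing tests therefore demonstrate the machinery is correct under
the stated structure, not that real-data estimates would be identical.

## Estimation choices

* **Usual intake** uses a two-component method-of-moments variance split on
  the log scale instead of the full NCI mixed-model method: within-person
  variance is the mean per-person sample variance across repeat days;
  between-person variance subtracts `σ²_w · mean(1/k_i)` from the variance
  of person means (clamped at zero).  Downstream stages consume only
  stratum means and variances, so the full Box–Cox mixed model would add
  machinery without changing any reported quantity.  With single-day data
  the within component is set to zero with a warning.
* **Partial compliance** is applied as an expectation at the record level
  (a convex combination) rather than resampling compliant schools:
  identical mean, lower Monte Carlo noise.
* **Monte Carlo.** Effect sizes and intake deltas are normal on the natural
  scale (SE = CI width / 3.92); RRs are normal on the log scale; mortality,
  DALY and cost totals get lognormal mean-1 scalers per disease group
  (log-SDs 0.02/0.02/0.05).  All draws are independent — no correlation
  structure is asserted anywhere.  Baseline habitual means are not
  resampled: they enter only percent-change reporting, not the burden
  chain, so resampling them would add noise to a purely descriptive
  quantity.  Percentiles use linear interpolation between closest ranks
  (`stats::quantile` type 7), fixed for bit-reproducibility.  Obesity-related
  cancer sites share one meta-analytic BMI-RR draw rather than sampling 12
  independent copies of the same estimate.
* **Degenerate inputs.** Zero-variance parameters collapse every draw to
  the point estimates end-to-end; physically impossible requests (negative
  dispersions, n < 1, baselines ≤ 0, waste ≥ 1) are rejected with typed
  errors rather than silently clamped.

## Problem sizes

The analysis drivers and the acceptance script use 20,000 simulated
children (two recall days each) and 1000 Monte Carlo draws — the same draw
count as the reported uncertainty intervals.  The test suite uses smaller
populations (500–20,000) and 40–1000 draws depending on what each property
needs; the variance-split recovery check uses 5000 persons, at which the
method-of-moments estimator is comfortably within 15% of truth.

## Known limitations

No life-table projection, age-cohort dynamics, discounting, or secular
trend adjustment; burden attribution is cross-sectional in the CRA sense.
Negative PIFs (harmful shifts in a draw) are allowed end-to-end, so
uncertainty intervals can span zero.  The adult placeholder inputs make
absolute burden numbers illustrative; orderings (partial ≤ full compliance,
monotonicity in κ) are the meaningful outputs at desk scale.
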
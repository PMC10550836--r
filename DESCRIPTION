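Package: schoolmealcra
Title: Comparative Risk Assessment of School Meal Nutrition Standards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation-based comparative risk assessment (CRA) of aligning
    US school-meal nutrition standards for added sugars, sodium, and whole
    grains with the 2020-2025 Dietary Guidelines for Americans. Generates
    synthetic child dietary microdata and adult mortality/DALY/cost tables,
    derives per-meal nutrient limits from calorie allowances and the sodium
    CDRR, constructs counterfactual school-meal intakes under full or partial
    compliance with plate waste, converts habitual intake changes into
    childhood BMI and blood-pressure changes, propagates persistent dietary
    change into adult strata through direct and mediated log-linear relative
    risks, combines potential impact fractions multiplicatively, attributes
    deaths, DALYs, and costs, and quantifies uncertainty by seeded Monte
    Carlo with 95% uncertainty intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
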
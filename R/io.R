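#' Schemas for the pipeline's exchange tables
#'
#' Named column-type vectors (`c` = character, `d` = double, `i` = integer)
#' for each table the pipeline reads or writes.
#' @param name table name: `"child_records"`, `"standards"`,
#'   `"intake_changes"`, `"child_outcomes"`, `"adult_intakes"`, `"rates"`,
#'   `"dalys"`, `"costs"`, `"burden"`
#' @return named character vector of column types
#' @export
table_schema <- function(name) {
  schemas <- list(
    child_records = c(
      person_id = "c", age_y = "i", sex = "c", race_eth = "c",
      grade_band = "c", survey_weight = "d",
      breakfast_participation = "d", lunch_participation = "d",
      bmi = "d", sbp = "d", dbp = "d", day = "i",
      school_breakfast_added_sugar_g = "d", school_breakfast_sodium_mg = "d",
      school_breakfast_whole_grain_g = "d", school_breakfast_total_grain_g = "d",
      school_lunch_added_sugar_g = "d", school_lunch_sodium_mg = "d",
      school_lunch_whole_grain_g = "d", school_lunch_total_grain_g = "d",
      other_added_sugar_g = "d", other_sodium_mg = "d",
      other_whole_grain_g = "d", other_total_grain_g = "d"),
    standards = c(grade_band = "c", meal = "c", added_sugar_max_g = "d",
                  sodium_max_mg = "d", whole_grain_rich_fraction = "d"),
    intake_changes = c(grade_band = "c", factor = "c", scenario = "c",
                       baseline_mean = "d", baseline_se = "d",
                       delta_mean = "d", se_delta = "d", percent_change = "d"),
    child_outcomes = c(grade_band = "c", outcome = "c", delta_point = "d",
                       ui_low = "d", ui_high = "d"),
    adult_intakes = c(age_band = "c", sex = "c", race_eth = "c",
                      population_count = "d", factor = "c", mean_intake = "d"),
    rates = c(age_band = "c", sex = "c", race_eth = "c",
              population_count = "d", disease = "c", deaths_per_year = "d"),
    dalys = c(age_band = "c", sex = "c", disease = "c", dalys_per_year = "d"),
    costs = c(disease_group = "c", direct_cost_busd2019 = "d",
              indirect_cost_busd2019 = "d"),
    burden = c(scenario = "c", kappa = "d", disease_group = "c",
               quantity = "c", point = "d", median = "d",
               ui_low = "d", ui_high = "d")
  )
  if (is.null(schemas[[name]])) stop_parameter("unknown table schema: ", name)
  schemas[[name]]
}

#' Write a pipeline table as CSV with provenance comments
#'
#' Plain UTF-8 comma-separated text with a header row, preceded by `#`
#' comment lines carrying the run's config hash, seed, and package version
#' so every emitted table is traceable to its run.
#' @param df data frame
#' @param path output path
#' @param meta optional named list written as `# key: value` comment lines
#' @return `path`, invisibly
#' @export
write_table <- function(df, path, meta = NULL) {
  lines <- character(0)
  if (!is.null(meta)) {
    lines <- sprintf("# %s: %s", names(meta),
                     vapply(meta, function(x) paste(format(x), collapse = " "), ""))
  }
  writeLines(lines, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and validate a pipeline table
#'
#' Strict schema validation: the header must contain exactly the schema's
#' columns (unknown or missing columns are errors naming the offenders) and
#' every column must parse as its declared type.  `#` comment lines are
#' skipped.
#' @param path CSV path
#' @param schema named type vector from [table_schema()] (or a schema name)
#' @return tibble with typed columns
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1 && is.null(names(schema))) {
    schema <- table_schema(schema)
  }
  header <- names(readr::read_csv(path, comment = "#", n_max = 0,
                                  show_col_types = FALSE))
  unknown <- setdiff(header, names(schema))
  missing <- setdiff(names(schema), header)
  if (length(unknown) || length(missing)) {
    stop_schema(
      "table schema mismatch in ", path,
      if (length(missing)) paste0("; missing column(s): ",
                                  paste(missing, collapse = ", ")),
      if (length(unknown)) paste0("; unknown column(s): ",
                                  paste(unknown, collapse = ", ")))
  }
  types <- paste(unname(schema[header]), collapse = "")
  df <- readr::read_csv(path, comment = "#",
                        col_types = types, show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop_schema("type error(s) reading ", path, ": ",
                paste(unique(probs$expected), collapse = ", "))
  }
  df[names(schema)]
}
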
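#' The snowflake-schema staging data model
#'
#' A `staging_bundle` holds one study's longitudinal survey data prior to
#' transformation: households, individuals, data-collection waves, variable
#' definitions, and item responses, as tibbles. The model is file-backed — one
#' UTF-8 comma-separated file per table, ISO-8601 dates, empty string meaning
#' absent — replacing the live relational staging server at desk scale.
#'
#' @param study_id Study label.
#' @param households Tibble: `household_id`, `location_label`, `latitude`,
#'   `longitude`.
#' @param individuals Tibble: `individual_id`, `household_id`, `sex_code`,
#'   `birth_date`, `race_code`, `ethnicity_code`, `marital_status_code`.
#' @param waves Tibble: `wave_id`, `study_id`, `wave_index`, `wave_date`.
#' @param variables Tibble: `variable_id`, `instrument_id`, `value_kind`
#'   (`quantitative`, `categorical` or `free_text`), `unit_label`,
#'   `allowed_values` (pipe-separated category list), `is_diagnosis`.
#' @param responses Tibble: `individual_id`, `wave_id`, `variable_id`,
#'   `raw_value`, `numeric_value`.
#' @return An object of class `staging_bundle`.
#' @export
staging_bundle <- function(study_id,
                           households = empty_staging_table("households"),
                           individuals = empty_staging_table("individuals"),
                           waves = empty_staging_table("waves"),
                           variables = empty_staging_table("variables"),
                           responses = empty_staging_table("responses")) {
  b <- new_staging_bundle(study_id, households, individuals, waves, variables, responses)
  validate_staging_bundle(b)
  b
}

new_staging_bundle <- function(study_id, households, individuals, waves,
                               variables, responses) {
  schemas <- staging_schemas()
  tables <- list(
    households = households, individuals = individuals, waves = waves,
    variables = variables, responses = responses
  )
  tables <- purrr::imap(tables, function(tbl, name) {
    assert_columns(tbl, names(schemas[[name]]), paste0("staging table '", name, "'"))
    as_tibble(tbl)[, names(schemas[[name]])]
  })
  structure(
    c(list(study_id = study_id), tables),
    class = "staging_bundle"
  )
}

validate_staging_bundle <- function(b) {
  dup <- function(x) x[!is.na(x)][duplicated(x[!is.na(x)])]
  if (length(dup(b$households$household_id)) > 0) {
    abort("duplicate household_id in households")
  }
  if (length(dup(b$individuals$individual_id)) > 0) {
    abort("duplicate individual_id in individuals")
  }
  key <- paste(b$waves$study_id, b$waves$wave_index)
  if (anyDuplicated(key)) abort("duplicate (study_id, wave_index) in waves")
  bad_order <- b$waves %>%
    dplyr::arrange(.data$study_id, .data$wave_index) %>%
    dplyr::group_by(.data$study_id) %>%
    dplyr::filter(dplyr::row_number() > 1 &
      .data$wave_date < dplyr::lag(.data$wave_date)) %>%
    dplyr::ungroup()
  if (nrow(bad_order) > 0) {
    abort("wave_date must be non-decreasing in wave_index within a study")
  }
  ok_kinds <- c("quantitative", "categorical", "free_text")
  if (!all(b$variables$value_kind %in% ok_kinds)) {
    abort("value_kind must be one of quantitative, categorical, free_text")
  }
  invisible(b)
}

staging_schemas <- function() {
  list(
    households = c(
      household_id = "c", location_label = "c", latitude = "d", longitude = "d"
    ),
    individuals = c(
      individual_id = "c", household_id = "c", sex_code = "c", birth_date = "D",
      race_code = "c", ethnicity_code = "c", marital_status_code = "c"
    ),
    waves = c(wave_id = "c", study_id = "c", wave_index = "i", wave_date = "D"),
    variables = c(
      variable_id = "c", instrument_id = "c", value_kind = "c",
      unit_label = "c", allowed_values = "c", is_diagnosis = "l"
    ),
    responses = c(
      individual_id = "c", wave_id = "c", variable_id = "c",
      raw_value = "c", numeric_value = "d"
    )
  )
}

empty_staging_table <- function(name) {
  schema <- staging_schemas()[[name]]
  proto <- list(
    c = character(), d = double(), i = integer(), D = as.Date(character()),
    l = logical()
  )
  as_tibble(lapply(schema, function(t) proto[[t]]))
}

staging_table_names <- function() names(staging_schemas())

#' @export
print.staging_bundle <- function(x, ...) {
  cat("<staging_bundle> study:", x$study_id, "\n")
  for (nm in staging_table_names()) {
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  }
  excl <- staging_exclusions(x)
  if (!is.null(excl) && nrow(excl) > 0) {
    cat("  (", sum(excl$n), "rows excluded on load for dangling references )\n")
  }
  invisible(x)
}

#' Exclusion report attached to a loaded bundle
#'
#' Rows with dangling references are excluded (never repaired) when a bundle is
#' loaded from disk; this accessor returns the per-table exclusion counts.
#'
#' @param bundle A `staging_bundle`.
#' @return A tibble `table`, `rule`, `n`, or `NULL` when the bundle was built
#'   in memory.
#' @export
staging_exclusions <- function(bundle) {
  attr(bundle, "exclusions")
}

# Drop rows whose references do not resolve; returns list(bundle, exclusions).
drop_dangling <- function(b) {
  excl <- list()
  note <- function(table, rule, n) {
    if (n > 0) excl[[length(excl) + 1]] <<- tibble(table = table, rule = rule, n = as.integer(n))
  }

  keep <- is.na(b$individuals$household_id) |
    b$individuals$household_id %in% b$households$household_id
  note("individuals", "dangling_household_reference", sum(!keep))
  b$individuals <- b$individuals[keep, ]

  r <- b$responses
  ok_ind <- r$individual_id %in% b$individuals$individual_id
  ok_wave <- r$wave_id %in% b$waves$wave_id
  ok_var <- r$variable_id %in% b$variables$variable_id
  note("responses", "dangling_individual_reference", sum(!ok_ind))
  note("responses", "dangling_wave_reference", sum(ok_ind & !ok_wave))
  note("responses", "dangling_variable_reference", sum(ok_ind & ok_wave & !ok_var))
  b$responses <- r[ok_ind & ok_wave & ok_var, ]

  excl <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble(table = character(), rule = character(), n = integer())
  list(bundle = b, exclusions = excl)
}

staging_col_types <- function(name) {
  schema <- staging_schemas()[[name]]
  do.call(readr::cols, as.list(setNames(unname(schema), names(schema))))
}

#' Load a staging bundle from a directory of delimited files
#'
#' Reads one comma-separated file per staging table (`households.csv`,
#' `individuals.csv`, `waves.csv`, `variables.csv`, `responses.csv`), then
#' enforces referential closure: rows with dangling references are excluded
#' with a warning and counted in the exclusion report (see
#' [staging_exclusions()]).
#'
#' @param path Directory containing the five staging files.
#' @param study_id Study label; defaults to the single `study_id` found in the
#'   waves table.
#' @return A referentially closed `staging_bundle`.
#' @export
load_staging <- function(path, study_id = NULL) {
  tables <- purrr::map(staging_table_names(), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) abort(sprintf("missing staging table file: %s", f))
    tbl <- readr::read_csv(
      f, col_types = staging_col_types(nm), na = "",
      locale = readr::locale(encoding = "UTF-8"), progress = FALSE
    )
    assert_columns(tbl, names(staging_schemas()[[nm]]), paste0("file '", f, "'"))
    tbl
  })
  names(tables) <- staging_table_names()

  if (is.null(study_id)) {
    ids <- unique(tables$waves$study_id)
    study_id <- if (length(ids) == 1) ids else NA_character_
  }
  b <- new_staging_bundle(
    study_id, tables$households, tables$individuals, tables$waves,
    tables$variables, tables$responses
  )
  closed <- drop_dangling(b)
  if (nrow(closed$exclusions) > 0) {
    warn(sprintf(
      "%d row(s) excluded for dangling references (see staging_exclusions())",
      sum(closed$exclusions$n)
    ))
  }
  out <- closed$bundle
  attr(out, "exclusions") <- closed$exclusions
  out
}

#' Write a staging bundle to a directory of delimited files
#'
#' One UTF-8 CSV per table, ISO-8601 dates, empty string for absent values.
#' Round-trips losslessly through [load_staging()].
#'
#' @param bundle A `staging_bundle`.
#' @param path Target directory (created if needed).
#' @return Invisibly, a file manifest tibble: `file`, `path`, `n_rows`, `md5`.
#' @export
write_staging <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  manifest <- purrr::map(staging_table_names(), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(bundle[[nm]], f, na = "", progress = FALSE)
    tibble(
      file = paste0(nm, ".csv"), path = f, n_rows = nrow(bundle[[nm]]),
      md5 = unname(tools::md5sum(f))
    )
  })
  invisible(dplyr::bind_rows(manifest))
}
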
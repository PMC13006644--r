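#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats setNames
NULL

# Single place for the empty error-log / summary schemas so every producer agrees.
empty_error_log <- function() {
  tibble(
    step = character(), table = character(), row_key = character(),
    rule = character(), action = character()
  )
}

empty_execution_summary <- function() {
  tibble(
    step = character(), rows_in = integer(),
    rows_out = integer(), rows_excluded = integer()
  )
}

log_entry <- function(step, table, row_key, rule, action) {
  if (length(row_key) == 0) return(empty_error_log())
  tibble(
    step = step, table = table, row_key = as.character(row_key),
    rule = rule, action = action
  )
}

summary_row <- function(step, rows_in, rows_out) {
  tibble(
    step = step, rows_in = as.integer(rows_in), rows_out = as.integer(rows_out),
    rows_excluded = as.integer(rows_in - rows_out)
  )
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# Composite response key shared by the injection ledger, the ETL error log and
# the QC reconciliation so corrupted cells can be traced end to end.
response_key <- function(individual_id, wave_id, variable_id) {
  paste(individual_id, wave_id, variable_id, sep = "::")
}
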
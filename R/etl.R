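#' ETL configuration
#'
#' Tunable behaviour of the staging-to-CDM transformation. All
#' `*_type_concept_id` fields take one uniform configurable value (default:
#' the survey type concept); demographic source codes are mapped through
#' explicit code maps, with absent or unknown codes coalesced to the
#' "no matching concept" id 0 and ledgered; condition rows are derived only
#' from explicit screening-threshold rules (composite score at or above a
#' cut-point emits a condition occurrence), since survey data carry no
#' diagnoses of their own. The reference date is the pipeline's "today" for
#' plausibility cleaning and is never read from the wall clock.
#'
#' @param reference_date Date; no event or birth date may lie after it.
#' @param type_concept_id Uniform `*_type_concept_id` (default 32862, survey).
#' @param visit_concept_id Concept for the wave visit (default 581476,
#'   home visit).
#' @param unknown_concept_id Fallback concept for unmapped codes (default 0).
#' @param gender_map,race_map,ethnicity_map Named numeric vectors mapping
#'   source codes to concept ids.
#' @param emit_items,emit_scores Route item-level responses / composite scores
#'   into the CDM (both on by default: items to the domain the plan chose,
#'   composites to Measurement).
#' @param condition_rules Tibble `instrument_id`, `min_total`,
#'   `condition_concept_id`: screening thresholds that derive condition rows.
#'   Defaults: PHQ-9 >= 10 emits depressive disorder (440383), GAD-7 >= 10
#'   emits anxiety disorder (442077) — the conventional moderate cut-points.
#' @param prorate Prorate incomplete instruments (off by default; see
#'   [score_instrument()]).
#' @return An object of class `etl_config`.
#' @export
etl_config <- function(reference_date = "2024-01-01",
                       type_concept_id = 32862,
                       visit_concept_id = 581476,
                       unknown_concept_id = 0,
                       gender_map = c(F = 8532, M = 8507),
                       race_map = c(black = 8516, white = 8527),
                       ethnicity_map = c(not_hispanic = 38003564, hispanic = 38003563),
                       emit_items = TRUE,
                       emit_scores = TRUE,
                       condition_rules = NULL,
                       prorate = FALSE) {
  if (is.null(condition_rules)) {
    condition_rules <- tibble(
      instrument_id = c("PHQ-9", "GAD-7"),
      min_total = c(10, 10),
      condition_concept_id = c(440383, 442077)
    )
  }
  structure(
    list(
      reference_date = as_iso_date(reference_date),
      type_concept_id = type_concept_id, visit_concept_id = visit_concept_id,
      unknown_concept_id = unknown_concept_id,
      gender_map = gender_map, race_map = race_map, ethnicity_map = ethnicity_map,
      emit_items = emit_items, emit_scores = emit_scores,
      condition_rules = condition_rules, prorate = prorate
    ),
    class = "etl_config"
  )
}

#' Null implausible dates and ledger each change
#'
#' Applies the two temporal consistency rules: a date after `reference_date`
#' is implausible (future event, or future birth when no birth lookup is
#' given), and an event date before the person's birth date is implausible.
#' Violating dates are set to `NA` and one log entry per nulled cell is
#' returned; all other rows are unchanged. Violations are data, not faults —
#' this function never errors.
#'
#' @param records Tibble containing `date_col` and `key_col`.
#' @param birth_lookup Optional tibble `individual_id`, `birth_date`; when
#'   given, `records` must carry `individual_id` and the event-before-birth
#'   rule is applied.
#' @param reference_date The pipeline's "today".
#' @param date_col,key_col Column names of the date being cleaned and of the
#'   row key used in the log.
#' @param step,table Labels for the log entries.
#' @return A list: `records` (dates nulled) and `log` (error-log tibble).
#' @export
clean_dates <- function(records, birth_lookup = NULL, reference_date,
                        date_col = "event_date", key_col = "row_key",
                        step = "clean_dates", table = "records") {
  reference_date <- as_iso_date(reference_date)
  dates <- records[[date_col]]
  keys <- as.character(records[[key_col]])
  logs <- list()

  future_rule <- if (is.null(birth_lookup) && grepl("birth", date_col)) {
    "future_birth_date"
  } else "future_event_date"
  future <- !is.na(dates) & dates > reference_date
  if (any(future)) {
    logs[[length(logs) + 1]] <- log_entry(step, table, keys[future], future_rule, "nulled")
    dates[future] <- as.Date(NA)
  }

  if (!is.null(birth_lookup)) {
    birth <- birth_lookup$birth_date[match(records$individual_id,
      birth_lookup$individual_id)]
    before <- !is.na(dates) & !is.na(birth) & dates < birth
    if (any(before)) {
      logs[[length(logs) + 1]] <- log_entry(step, table, keys[before],
        "event_before_birth", "nulled")
      dates[before] <- as.Date(NA)
    }
  }
  records[[date_col]] <- dates
  list(
    records = records,
    log = if (length(logs) > 0) dplyr::bind_rows(logs) else empty_error_log()
  )
}

#' Coalesce absent or unknown demographic codes to a default concept
#'
#' Maps `sex_code`, `race_code` and `ethnicity_code` through the configured
#' code maps, replacing absent or unmappable codes by the configured
#' unknown-concept id (0 by default, the OMOP convention for "no matching
#' concept"). Every replacement is ledgered with action `remapped`.
#'
#' @param records Individuals-shaped tibble (`individual_id`, `sex_code`,
#'   `race_code`, `ethnicity_code`).
#' @param config An [etl_config()].
#' @return A list: `records` (with `gender_concept_id`, `race_concept_id`,
#'   `ethnicity_concept_id` appended) and `log`.
#' @export
apply_demographic_defaults <- function(records, config = etl_config()) {
  logs <- list()
  map_one <- function(codes, map, field) {
    out <- unname(map[codes])
    absent <- is.na(codes)
    unknown <- !absent & is.na(out)
    if (any(absent)) {
      logs[[length(logs) + 1]] <<- log_entry("person", "person",
        records$individual_id[absent],
        paste0("missing_", field, "_code"), "remapped")
    }
    if (any(unknown)) {
      logs[[length(logs) + 1]] <<- log_entry("person", "person",
        records$individual_id[unknown],
        paste0("unmapped_", field, "_code"), "remapped")
    }
    out[is.na(out)] <- config$unknown_concept_id
    out
  }
  records$gender_concept_id <- map_one(records$sex_code, config$gender_map, "gender")
  records$race_concept_id <- map_one(records$race_code, config$race_map, "race")
  records$ethnicity_concept_id <- map_one(records$ethnicity_code,
    config$ethnicity_map, "ethnicity")
  list(
    records = records,
    log = if (length(logs) > 0) dplyr::bind_rows(logs) else empty_error_log()
  )
}

#' Run the staging-to-CDM transformation
#'
#' Populates the OMOP CDM tables in dependency order — location, (empty)
#' care_site and provider, person, visit_occurrence, then measurement,
#' observation and condition_occurrence — applying the cleaning rules and
#' recording a complete audit trail: one error-log entry per nulled, excluded
#' or remapped cell, and one execution-summary row per step with
#' `rows_in = rows_out + rows_excluded`. One visit is emitted per
#' (individual, wave) with at least one response; composite instrument scores
#' go to Measurement and item-level responses to the domain the mapping plan
#' chose (Observation by default). Placeholder identifiers are never invented
#' for missing required keys: such rows are excluded and logged.
#'
#' @param bundle A `staging_bundle` (possibly corrupted; violations become
#'   log entries, not errors).
#' @param plan A `mapping_plan` compiled against `bundle`.
#' @param registry The `concept_registry` the plan references.
#' @param config An [etl_config()].
#' @return A `cdm_bundle`: `tables` (named list of CDM tibbles), `error_log`,
#'   `execution_summary`, and `metadata`.
#' @export
run_etl <- function(bundle, plan, registry, config = etl_config()) {
  stopifnot(inherits(plan, "mapping_plan"))
  # fatal before any write: the plan must resolve against the registry
  refs <- c(plan$entries$target_concept_id, plan$value_map$value_concept_id,
    plan$score_map$concept_id)
  unresolved <- setdiff(refs, registry$concepts$concept_id)
  if (length(unresolved) > 0) {
    abort(sprintf("mapping plan references concept id(s) absent from the registry: %s",
      paste(format(unresolved, scientific = FALSE), collapse = ", ")))
  }

  logs <- list()
  sums <- list()
  add_log <- function(x) if (nrow(x) > 0) logs[[length(logs) + 1]] <<- x
  add_sum <- function(x) sums[[length(sums) + 1]] <<- x

  ## --- location -----------------------------------------------------------
  hh <- dplyr::arrange(bundle$households, .data$household_id)
  location <- tibble(
    location_id = seq_len(nrow(hh)),
    city = hh$location_label,
    latitude = hh$latitude, longitude = hh$longitude,
    location_source_value = hh$household_id
  )
  add_sum(summary_row("location", nrow(hh), nrow(location)))

  care_site <- tibble(care_site_id = integer(), care_site_name = character(),
    location_id = integer())
  provider <- tibble(provider_id = integer(), provider_name = character(),
    specialty_concept_id = numeric())
  add_sum(summary_row("care_site", 0, 0))
  add_sum(summary_row("provider", 0, 0))

  ## --- person -------------------------------------------------------------
  ind <- bundle$individuals
  n_in <- nrow(ind)

  null_id <- is.na(ind$individual_id) | ind$individual_id == ""
  if (any(null_id)) {
    add_log(log_entry("person", "person",
      paste0("individuals_row_", which(null_id)), "null_person_id", "excluded"))
  }
  ind <- ind[!null_id, ]

  cleaned <- clean_dates(ind, birth_lookup = NULL,
    reference_date = config$reference_date, date_col = "birth_date",
    key_col = "individual_id", step = "person", table = "person")
  ind <- cleaned$records
  add_log(cleaned$log)

  no_birth <- is.na(ind$birth_date)
  if (any(no_birth)) {
    add_log(log_entry("person", "person", ind$individual_id[no_birth],
      "missing_birth_date", "excluded"))
  }
  ind <- ind[!no_birth, ]

  demo <- apply_demographic_defaults(ind, config)
  ind <- demo$records
  add_log(demo$log)

  ind <- dplyr::arrange(ind, .data$individual_id)
  person <- tibble(
    person_id = seq_len(nrow(ind)),
    gender_concept_id = ind$gender_concept_id,
    year_of_birth = as.integer(format(ind$birth_date, "%Y")),
    month_of_birth = as.integer(format(ind$birth_date, "%m")),
    day_of_birth = as.integer(format(ind$birth_date, "%d")),
    race_concept_id = ind$race_concept_id,
    ethnicity_concept_id = ind$ethnicity_concept_id,
    location_id = location$location_id[match(ind$household_id,
      location$location_source_value)],
    person_source_value = ind$individual_id,
    gender_source_value = ind$sex_code,
    race_source_value = ind$race_code,
    ethnicity_source_value = ind$ethnicity_code
  )
  add_sum(summary_row("person", n_in, nrow(person)))

  birth_lookup <- tibble(individual_id = ind$individual_id,
    birth_date = ind$birth_date)

  ## --- visit_occurrence ---------------------------------------------------
  cand <- bundle$responses %>%
    dplyr::distinct(.data$individual_id, .data$wave_id) %>%
    dplyr::left_join(bundle$waves[, c("wave_id", "wave_date")], by = "wave_id") %>%
    dplyr::mutate(visit_key = paste(.data$individual_id, .data$wave_id, sep = "::")) %>%
    dplyr::arrange(.data$individual_id, .data$wave_id)
  n_in <- nrow(cand)

  orphan <- !cand$individual_id %in% person$person_source_value
  if (any(orphan)) {
    add_log(log_entry("visit_occurrence", "visit_occurrence",
      cand$visit_key[orphan], "orphaned_person_reference", "excluded"))
  }
  cand <- cand[!orphan, ]

  cleaned <- clean_dates(cand, birth_lookup = birth_lookup,
    reference_date = config$reference_date, date_col = "wave_date",
    key_col = "visit_key", step = "visit_occurrence", table = "visit_occurrence")
  cand <- cleaned$records
  add_log(cleaned$log)

  no_date <- is.na(cand$wave_date)
  if (any(no_date)) {
    add_log(log_entry("visit_occurrence", "visit_occurrence",
      cand$visit_key[no_date], "missing_visit_date", "excluded"))
  }
  cand <- cand[!no_date, ]

  cand$person_id <- person$person_id[match(cand$individual_id,
    person$person_source_value)]
  cand <- dplyr::arrange(cand, .data$person_id, .data$wave_date, .data$wave_id)
  visit_occurrence <- tibble(
    visit_occurrence_id = seq_len(nrow(cand)),
    person_id = cand$person_id,
    visit_concept_id = config$visit_concept_id,
    visit_start_date = cand$wave_date,
    visit_end_date = cand$wave_date,
    visit_type_concept_id = config$type_concept_id,
    visit_source_value = cand$visit_key
  )
  add_sum(summary_row("visit_occurrence", n_in, nrow(visit_occurrence)))

  visit_lookup <- tibble(
    individual_id = cand$individual_id, wave_id = cand$wave_id,
    visit_occurrence_id = visit_occurrence$visit_occurrence_id,
    person_id = visit_occurrence$person_id,
    visit_date = visit_occurrence$visit_start_date
  )

  ## --- events: responses annotated with plan decisions ---------------------
  resp <- bundle$responses %>%
    dplyr::left_join(plan$entries, by = "variable_id") %>%
    dplyr::mutate(row_key = response_key(.data$individual_id, .data$wave_id,
      .data$variable_id))

  ## --- measurement --------------------------------------------------------
  scores <- if (config$emit_scores) {
    wave_scores(bundle, on_invalid = "treat_missing", prorate = config$prorate) %>%
      dplyr::filter(.data$complete)
  } else {
    tibble(individual_id = character(), wave_id = character(),
      instrument_id = character(), total = numeric())
  }
  scores$row_key <- paste(scores$individual_id, scores$wave_id,
    scores$instrument_id, sep = "::")
  meas_items <- resp %>% dplyr::filter(!is.na(.data$target_domain) &
    .data$target_domain == "Measurement")
  n_in <- nrow(scores) + nrow(meas_items)

  drop_orphans <- function(events, step) {
    events$person_id <- person$person_id[match(events$individual_id,
      person$person_source_value)]
    orphan <- is.na(events$person_id)
    if (any(orphan)) {
      add_log(log_entry(step, step, events$row_key[orphan],
        "orphaned_person_reference", "excluded"))
    }
    events <- events[!orphan, ]
    events <- dplyr::left_join(events,
      visit_lookup[, c("individual_id", "wave_id", "visit_occurrence_id", "visit_date")],
      by = c("individual_id", "wave_id"))
    no_visit <- is.na(events$visit_occurrence_id)
    if (any(no_visit)) {
      add_log(log_entry(step, step, events$row_key[no_visit],
        "orphaned_visit_reference", "excluded"))
    }
    events[!no_visit, ]
  }

  unmapped_score <- !scores$instrument_id %in% plan$score_map$instrument_id
  if (any(unmapped_score)) {
    add_log(log_entry("measurement", "measurement",
      scores$row_key[unmapped_score], "unmapped_score_concept", "excluded"))
  }
  scores <- scores[!unmapped_score, ]
  scores <- drop_orphans(scores, "measurement")
  scores <- dplyr::left_join(scores, plan$score_map, by = "instrument_id")

  meas_items <- drop_orphans(meas_items, "measurement")

  meas_rows <- dplyr::bind_rows(
    if (nrow(scores) > 0) tibble(
      person_id = scores$person_id,
      measurement_concept_id = scores$concept_id,
      measurement_date = scores$visit_date,
      value_as_number = scores$total,
      value_as_concept_id = NA_real_,
      unit_concept_id = scores$unit_concept_id,
      visit_occurrence_id = scores$visit_occurrence_id,
      measurement_source_value = scores$row_key,
      instrument_id = scores$instrument_id
    ),
    if (nrow(meas_items) > 0) tibble(
      person_id = meas_items$person_id,
      measurement_concept_id = meas_items$target_concept_id,
      measurement_date = meas_items$visit_date,
      value_as_number = meas_items$numeric_value,
      value_as_concept_id = NA_real_,
      unit_concept_id = meas_items$unit_concept_id,
      visit_occurrence_id = meas_items$visit_occurrence_id,
      measurement_source_value = meas_items$row_key,
      instrument_id = NA_character_
    )
  )
  if (is.null(meas_rows) || nrow(meas_rows) == 0) {
    meas_rows <- tibble(
      person_id = integer(), measurement_concept_id = numeric(),
      measurement_date = as.Date(character()), value_as_number = numeric(),
      value_as_concept_id = numeric(), unit_concept_id = numeric(),
      visit_occurrence_id = integer(), measurement_source_value = character(),
      instrument_id = character()
    )
  }
  meas_rows <- dplyr::arrange(meas_rows, .data$person_id,
    .data$measurement_date, .data$measurement_source_value)
  measurement <- tibble(
    measurement_id = seq_len(nrow(meas_rows)),
    person_id = meas_rows$person_id,
    measurement_concept_id = meas_rows$measurement_concept_id,
    measurement_date = meas_rows$measurement_date,
    measurement_type_concept_id = rep(config$type_concept_id, nrow(meas_rows)),
    value_as_number = meas_rows$value_as_number,
    value_as_concept_id = meas_rows$value_as_concept_id,
    unit_concept_id = meas_rows$unit_concept_id,
    visit_occurrence_id = meas_rows$visit_occurrence_id,
    measurement_source_value = meas_rows$measurement_source_value
  )
  add_sum(summary_row("measurement", n_in, nrow(measurement)))

  ## --- observation --------------------------------------------------------
  if (config$emit_items) {
    obs_cand <- resp %>% dplyr::filter(is.na(.data$target_domain) |
      .data$target_domain == "Observation")
  } else {
    obs_cand <- resp[0, ]
  }
  n_in <- nrow(obs_cand)

  unmapped <- is.na(obs_cand$target_domain)
  if (any(unmapped)) {
    add_log(log_entry("observation", "observation", obs_cand$row_key[unmapped],
      "unmapped_variable", "excluded"))
  }
  obs_cand <- obs_cand[!unmapped, ]
  obs_cand <- drop_orphans(obs_cand, "observation")

  # value handling: numeric responses keep value_as_number; categorical labels
  # go through the value map, unknown codes coalesce to the unknown concept
  vm_key <- paste(plan$value_map$variable_id, plan$value_map$value_label, sep = "\r")
  obs_key <- paste(obs_cand$variable_id, obs_cand$raw_value, sep = "\r")
  mapped_value <- plan$value_map$value_concept_id[match(obs_key, vm_key)]
  has_numeric <- !is.na(obs_cand$numeric_value)
  needs_value_concept <- !has_numeric & !is.na(obs_cand$raw_value)
  unmapped_code <- needs_value_concept & is.na(mapped_value)
  # free-text variables are carried as strings, not codes
  var_kind <- bundle$variables$value_kind[match(obs_cand$variable_id,
    bundle$variables$variable_id)]
  free_text <- var_kind == "free_text"
  unmapped_code <- unmapped_code & !free_text
  if (any(unmapped_code)) {
    add_log(log_entry("observation", "observation",
      obs_cand$row_key[unmapped_code], "unmapped_code", "remapped"))
  }
  value_concept <- ifelse(needs_value_concept & !free_text,
    ifelse(is.na(mapped_value), config$unknown_concept_id, mapped_value),
    NA_real_)

  obs_cand <- dplyr::arrange(
    dplyr::mutate(obs_cand, value_as_concept_id = value_concept,
      value_as_string = ifelse(free_text, .data$raw_value, NA_character_)),
    .data$person_id, .data$visit_date, .data$row_key
  )
  observation <- tibble(
    observation_id = seq_len(nrow(obs_cand)),
    person_id = obs_cand$person_id,
    observation_concept_id = obs_cand$target_concept_id,
    observation_date = obs_cand$visit_date,
    observation_type_concept_id = rep(config$type_concept_id, nrow(obs_cand)),
    value_as_number = obs_cand$numeric_value,
    value_as_concept_id = obs_cand$value_as_concept_id,
    value_as_string = obs_cand$value_as_string,
    visit_occurrence_id = obs_cand$visit_occurrence_id,
    observation_source_value = obs_cand$row_key
  )
  add_sum(summary_row("observation", n_in, nrow(observation)))

  ## --- condition_occurrence ----------------------------------------------
  cond_resp <- resp %>% dplyr::filter(!is.na(.data$target_domain) &
    .data$target_domain == "Condition")
  score_hits <- dplyr::inner_join(
    dplyr::mutate(measurement, instrument_id = meas_rows$instrument_id),
    config$condition_rules, by = "instrument_id"
  ) %>%
    dplyr::filter(!is.na(.data$value_as_number) &
      .data$value_as_number >= .data$min_total)
  n_in <- nrow(cond_resp) + nrow(score_hits)

  cond_resp <- drop_orphans(cond_resp, "condition_occurrence")

  cond_rows <- dplyr::bind_rows(
    if (nrow(score_hits) > 0) tibble(
      person_id = score_hits$person_id,
      condition_concept_id = score_hits$condition_concept_id,
      condition_start_date = score_hits$measurement_date,
      visit_occurrence_id = score_hits$visit_occurrence_id,
      condition_source_value = score_hits$measurement_source_value
    ),
    if (nrow(cond_resp) > 0) tibble(
      person_id = cond_resp$person_id,
      condition_concept_id = cond_resp$target_concept_id,
      condition_start_date = cond_resp$visit_date,
      visit_occurrence_id = cond_resp$visit_occurrence_id,
      condition_source_value = cond_resp$row_key
    )
  )
  if (is.null(cond_rows) || nrow(cond_rows) == 0) {
    cond_rows <- tibble(
      person_id = integer(), condition_concept_id = numeric(),
      condition_start_date = as.Date(character()), visit_occurrence_id = integer(),
      condition_source_value = character()
    )
  }
  cond_rows <- dplyr::arrange(cond_rows, .data$person_id,
    .data$condition_start_date, .data$condition_source_value)
  condition_occurrence <- tibble(
    condition_occurrence_id = seq_len(nrow(cond_rows)),
    person_id = cond_rows$person_id,
    condition_concept_id = cond_rows$condition_concept_id,
    condition_start_date = cond_rows$condition_start_date,
    condition_type_concept_id = rep(config$type_concept_id, nrow(cond_rows)),
    visit_occurrence_id = cond_rows$visit_occurrence_id,
    condition_source_value = cond_rows$condition_source_value
  )
  add_sum(summary_row("condition_occurrence", n_in, nrow(condition_occurrence)))

  new_cdm_bundle(
    tables = list(
      location = location, care_site = care_site, provider = provider,
      person = person, visit_occurrence = visit_occurrence,
      measurement = measurement, observation = observation,
      condition_occurrence = condition_occurrence
    ),
    error_log = if (length(logs) > 0) dplyr::bind_rows(logs) else empty_error_log(),
    execution_summary = dplyr::bind_rows(sums),
    metadata = list(
      study_id = bundle$study_id,
      reference_date = config$reference_date,
      mapping_coverage = plan$coverage
    )
  )
}

new_cdm_bundle <- function(tables, error_log, execution_summary, metadata = list()) {
  structure(
    list(tables = tables, error_log = error_log,
      execution_summary = execution_summary, metadata = metadata),
    class = "cdm_bundle"
  )
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat("<cdm_bundle>", if (!is.null(x$metadata$study_id)) x$metadata$study_id else "", "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-22s %7d rows\n", nm, nrow(x$tables[[nm]])))
  }
  cat(sprintf("  error_log: %d entries; execution_summary: %d steps\n",
    nrow(x$error_log), nrow(x$execution_summary)))
  invisible(x)
}

cdm_col_types <- function() {
  list(
    location = readr::cols(location_id = "i", city = "c", latitude = "d",
      longitude = "d", location_source_value = "c"),
    care_site = readr::cols(care_site_id = "i", care_site_name = "c",
      location_id = "i"),
    provider = readr::cols(provider_id = "i", provider_name = "c",
      specialty_concept_id = "d"),
    person = readr::cols(person_id = "i", gender_concept_id = "d",
      year_of_birth = "i", month_of_birth = "i", day_of_birth = "i",
      race_concept_id = "d", ethnicity_concept_id = "d", location_id = "i",
      person_source_value = "c", gender_source_value = "c",
      race_source_value = "c", ethnicity_source_value = "c"),
    visit_occurrence = readr::cols(visit_occurrence_id = "i", person_id = "i",
      visit_concept_id = "d", visit_start_date = "D", visit_end_date = "D",
      visit_type_concept_id = "d", visit_source_value = "c"),
    measurement = readr::cols(measurement_id = "i", person_id = "i",
      measurement_concept_id = "d", measurement_date = "D",
      measurement_type_concept_id = "d", value_as_number = "d",
      value_as_concept_id = "d", unit_concept_id = "d",
      visit_occurrence_id = "i", measurement_source_value = "c"),
    observation = readr::cols(observation_id = "i", person_id = "i",
      observation_concept_id = "d", observation_date = "D",
      observation_type_concept_id = "d", value_as_number = "d",
      value_as_concept_id = "d", value_as_string = "c",
      visit_occurrence_id = "i", observation_source_value = "c"),
    condition_occurrence = readr::cols(condition_occurrence_id = "i",
      person_id = "i", condition_concept_id = "d", condition_start_date = "D",
      condition_type_concept_id = "d", visit_occurrence_id = "i",
      condition_source_value = "c"),
    error_log = readr::cols(step = "c", table = "c", row_key = "c", rule = "c",
      action = "c"),
    execution_summary = readr::cols(step = "c", rows_in = "i", rows_out = "i",
      rows_excluded = "i")
  )
}

#' Write / read a CDM bundle as delimited files
#'
#' One comma-separated file per CDM table with OMOP-standard lowercase column
#' names and ISO-8601 dates, plus `error_log.csv` and
#' `execution_summary.csv`. Round-trips losslessly.
#'
#' @param cdm A `cdm_bundle`.
#' @param path Target directory.
#' @return `write_cdm`: invisibly, a manifest tibble (`file`, `path`,
#'   `n_rows`, `md5`); `read_cdm`: a `cdm_bundle`.
#' @export
write_cdm <- function(cdm, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  all_tables <- c(cdm$tables,
    list(error_log = cdm$error_log, execution_summary = cdm$execution_summary))
  manifest <- purrr::imap(all_tables, function(tbl, nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(tbl, f, na = "", progress = FALSE)
    tibble(file = paste0(nm, ".csv"), path = f, n_rows = nrow(tbl),
      md5 = unname(tools::md5sum(f)))
  })
  invisible(dplyr::bind_rows(manifest))
}

#' @rdname write_cdm
#' @param path Directory holding the CDM files.
#' @export
read_cdm <- function(path) {
  specs <- cdm_col_types()
  tbls <- purrr::imap(specs, function(spec, nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) abort(sprintf("missing CDM file: %s", f))
    readr::read_csv(f, col_types = spec, na = "", progress = FALSE)
  })
  new_cdm_bundle(
    tables = tbls[setdiff(names(tbls), c("error_log", "execution_summary"))],
    error_log = tbls$error_log,
    execution_summary = tbls$execution_summary
  )
}
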
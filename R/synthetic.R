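#' Configuration for a synthetic longitudinal survey study
#'
#' Describes one emulated multi-wave mental-health survey study: its roster
#' size, wave schedule, administered instruments and covariates, and
#' independent missingness rates. The defaults describe a mid-sized household
#' survey: two common screening instruments (PHQ-9 and GAD-7), twice-yearly
#' waves starting 2020-01-15, mild item missingness (5%) and complete
#' demographics. The reference "today" used for plausibility logic is a config
#' value, never the wall clock, so runs are reproducible.
#'
#' @param study_id Study label.
#' @param n_households,n_individuals,n_waves Roster sizes; `n_waves >= 1`.
#' @param instruments Instrument labels drawn from
#'   [instrument_definitions()]; unknown labels are fatal at generation time.
#' @param covariates Categorical covariate labels (packaged catalogue:
#'   `employment_status`, `education_level`, `residence_type`; unknown labels
#'   get a generic 3-level coding).
#' @param item_missingness Per-item probability a response is absent, in
#'   `[0, 1]`.
#' @param demographic_missingness Probability each optional demographic code
#'   (sex, race, ethnicity, marital status) is absent, in `[0, 1]`.
#' @param first_wave_date Date of wave 1 (ISO string or Date).
#' @param wave_interval_days Days between consecutive waves.
#' @param reference_date The study's "today"; birth dates are generated before
#'   it and future-date injection is defined against it.
#' @param seed Integer seed; identical configs generate byte-identical bundles.
#' @return An object of class `study_config`.
#' @export
study_config <- function(study_id = "synthetic_study",
                         n_households = 40,
                         n_individuals = 100,
                         n_waves = 2,
                         instruments = c("PHQ-9", "GAD-7"),
                         covariates = c("employment_status", "education_level"),
                         item_missingness = 0.05,
                         demographic_missingness = 0,
                         first_wave_date = "2020-01-15",
                         wave_interval_days = 182L,
                         reference_date = "2024-01-01",
                         seed = 1L) {
  stopifnot(
    n_waves >= 1, n_households >= 0, n_individuals >= 0,
    item_missingness >= 0, item_missingness <= 1,
    demographic_missingness >= 0, demographic_missingness <= 1
  )
  structure(
    list(
      study_id = study_id, n_households = as.integer(n_households),
      n_individuals = as.integer(n_individuals), n_waves = as.integer(n_waves),
      instruments = instruments, covariates = covariates,
      item_missingness = item_missingness,
      demographic_missingness = demographic_missingness,
      first_wave_date = as_iso_date(first_wave_date),
      wave_interval_days = as.integer(wave_interval_days),
      reference_date = as_iso_date(reference_date),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

covariate_catalogue <- function() {
  list(
    employment_status = c("employed", "unemployed", "student", "retired", "homemaker"),
    education_level = c("none", "primary", "secondary", "tertiary"),
    residence_type = c("rural", "peri_urban", "urban")
  )
}

covariate_levels <- function(label) {
  covariate_catalogue()[[label]] %||% c("level_1", "level_2", "level_3")
}

instrument_slug <- function(instrument_id) {
  gsub("[^a-z0-9]", "", tolower(instrument_id))
}

# Categorical item weights skewed toward low severity; truncated/renormalised
# to the instrument's response-range length.
item_weights <- function(n_levels) {
  w <- c(0.45, 0.25, 0.15, 0.09, 0.06)[seq_len(n_levels)]
  w / sum(w)
}

#' Generate a synthetic staging bundle for one study
#'
#' Builds a referentially closed [staging_bundle()]: `n_individuals`
#' individuals assigned uniformly to households; `n_waves` waves with strictly
#' increasing dates; for each individual x wave x instrument one item response
#' per item, drawn from a low-severity-skewed categorical distribution over
#' the instrument's response range; categorical covariates per individual x
#' wave. Missingness is applied independently per item at `item_missingness`
#' (a missing item simply has no response row). Identical configs (including
#' the seed) produce byte-identical bundles.
#'
#' @param config A [study_config()].
#' @return A `staging_bundle`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  # fail fast on unknown instrument labels
  purrr::walk(config$instruments, instrument_definition)

  withr::with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  n_hh <- config$n_households
  n_ind <- config$n_individuals

  households <- tibble(
    household_id = sprintf("HH%05d", seq_len(n_hh)),
    location_label = if (n_hh > 0) {
      sprintf("village_%02d", sample.int(max(1, ceiling(n_hh / 5)), n_hh, replace = TRUE))
    } else character(),
    latitude = round(stats::runif(n_hh, -4, 1), 5),
    longitude = round(stats::runif(n_hh, 33, 42), 5)
  )

  age_days <- round(stats::runif(n_ind, 18 * 365.25, 70 * 365.25))
  individuals <- tibble(
    individual_id = sprintf("IND%06d", seq_len(n_ind)),
    household_id = if (n_hh > 0 && n_ind > 0) {
      sample(households$household_id, n_ind, replace = TRUE)
    } else rep(NA_character_, n_ind),
    sex_code = sample(c("F", "M"), n_ind, replace = TRUE, prob = c(0.6, 0.4)),
    birth_date = config$first_wave_date - age_days,
    race_code = sample(c("black", "white"), n_ind, replace = TRUE, prob = c(0.92, 0.08)),
    ethnicity_code = sample(c("not_hispanic", "hispanic"), n_ind,
      replace = TRUE, prob = c(0.97, 0.03)),
    marital_status_code = sample(c("single", "married", "divorced", "widowed"),
      n_ind, replace = TRUE, prob = c(0.3, 0.5, 0.1, 0.1))
  )
  if (config$demographic_missingness > 0 && n_ind > 0) {
    for (col in c("sex_code", "race_code", "ethnicity_code", "marital_status_code")) {
      hit <- stats::runif(n_ind) < config$demographic_missingness
      individuals[[col]][hit] <- NA_character_
    }
  }

  waves <- tibble(
    wave_id = sprintf("%s_W%02d", config$study_id, seq_len(config$n_waves)),
    study_id = config$study_id,
    wave_index = seq_len(config$n_waves),
    wave_date = config$first_wave_date +
      (seq_len(config$n_waves) - 1L) * config$wave_interval_days
  )

  item_vars <- purrr::map(config$instruments, function(ins) {
    defn <- instrument_definition(ins)
    tibble(
      variable_id = sprintf("%s_item_%02d", instrument_slug(ins), seq_len(defn$n_items)),
      instrument_id = ins,
      value_kind = "categorical",
      unit_label = NA_character_,
      allowed_values = paste(seq(defn$item_min, defn$item_max), collapse = "|"),
      is_diagnosis = FALSE
    )
  })
  cov_vars <- purrr::map(config$covariates, function(cv) {
    tibble(
      variable_id = cv, instrument_id = NA_character_, value_kind = "categorical",
      unit_label = NA_character_,
      allowed_values = paste(covariate_levels(cv), collapse = "|"),
      is_diagnosis = FALSE
    )
  })
  variables <- dplyr::bind_rows(c(item_vars, cov_vars))
  if (nrow(variables) == 0) variables <- empty_staging_table("variables")

  responses <- generate_responses(config, individuals, waves, variables)

  new_staging_bundle(
    config$study_id, households, individuals, waves, variables, responses
  )
}

generate_responses <- function(config, individuals, waves, variables) {
  if (nrow(individuals) == 0 || nrow(waves) == 0 || nrow(variables) == 0) {
    return(empty_staging_table("responses"))
  }
  base <- tidyr::expand_grid(
    individual_id = individuals$individual_id,
    wave_id = waves$wave_id,
    variable_id = variables$variable_id
  ) %>%
    dplyr::left_join(
      variables[, c("variable_id", "instrument_id", "allowed_values")],
      by = "variable_id"
    )

  is_item <- !is.na(base$instrument_id)
  values <- character(nrow(base))

  # instrument items: integer categories skewed toward low severity
  for (ins in unique(base$instrument_id[is_item])) {
    defn <- instrument_definition(ins)
    lv <- seq(defn$item_min, defn$item_max)
    sel <- which(is_item & base$instrument_id == ins)
    values[sel] <- as.character(sample(lv, length(sel), replace = TRUE,
      prob = item_weights(length(lv))))
  }
  # covariates: uniform-ish draw with a mild preference for the first level
  for (cv in unique(base$variable_id[!is_item])) {
    lv <- strsplit(base$allowed_values[match(cv, base$variable_id)], "\\|")[[1]]
    sel <- which(!is_item & base$variable_id == cv)
    w <- rev(seq_along(lv)); w <- w / sum(w)
    values[sel] <- sample(lv, length(sel), replace = TRUE, prob = w)
  }

  keep <- rep(TRUE, nrow(base))
  if (config$item_missingness > 0) {
    keep[is_item] <- stats::runif(sum(is_item)) >= config$item_missingness
  }

  tibble(
    individual_id = base$individual_id[keep],
    wave_id = base$wave_id[keep],
    variable_id = base$variable_id[keep],
    raw_value = values[keep],
    numeric_value = suppressWarnings(as.numeric(values[keep]))
  ) %>%
    dplyr::arrange(.data$individual_id, .data$wave_id, .data$variable_id)
}

#' Error-injection specification
#'
#' Requested corruption counts per rule, used by [inject_errors()] to produce
#' a corrupted bundle together with a ground-truth ledger:
#' * `future_birth_dates` — birth dates moved after the reference date;
#' * `event_before_birth` — birth dates moved past the individual's earliest
#'   response wave, so that wave's events precede birth;
#' * `null_required_ids` — individual identifiers blanked out;
#' * `unmapped_codes` — categorical covariate responses replaced with a code
#'   outside the variable's category list;
#' * `out_of_range_items` — instrument item responses pushed above the item's
#'   response range.
#'
#' @param future_birth_dates,event_before_birth,null_required_ids,unmapped_codes,out_of_range_items
#'   Non-negative counts per rule.
#' @param seed Integer seed for target sampling.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(future_birth_dates = 0L, event_before_birth = 0L,
                       null_required_ids = 0L, unmapped_codes = 0L,
                       out_of_range_items = 0L, seed = 1L) {
  counts <- c(
    future_birth_dates = future_birth_dates, event_before_birth = event_before_birth,
    null_required_ids = null_required_ids, unmapped_codes = unmapped_codes,
    out_of_range_items = out_of_range_items
  )
  if (any(counts < 0)) abort("injection counts must be non-negative")
  structure(
    c(as.list(setNames(as.integer(counts), names(counts))),
      list(seed = as.integer(seed))),
    class = "error_spec"
  )
}

empty_ledger <- function() {
  tibble(rule = character(), table = character(), key = character())
}

#' Inject controlled errors into a staging bundle
#'
#' Returns a corrupted copy of `bundle` plus an injection ledger recording
#' exactly which (rule, table, key) cells were changed; rows that are not in
#' the ledger are byte-identical to the input. The ledger is the ground truth
#' against which ETL cleaning and quality-check detection are reconciled (see
#' [reconcile_injections()]). Insufficient eligible rows for a rule is fatal,
#' with a shortfall report. Rules that target individuals draw disjoint
#' targets.
#'
#' @param bundle A `staging_bundle`.
#' @param spec An [error_spec()].
#' @param reference_date The study's "today" (used by the future-birth rule);
#'   defaults to the latest wave date plus one year.
#' @return A list with elements `bundle` (corrupted `staging_bundle`) and
#'   `ledger` (tibble `rule`, `table`, `key`).
#' @export
inject_errors <- function(bundle, spec, reference_date = NULL) {
  stopifnot(inherits(spec, "error_spec"))
  if (is.null(reference_date)) {
    reference_date <- max(bundle$waves$wave_date) + 365
  }
  reference_date <- as_iso_date(reference_date)
  withr::with_seed(spec$seed, inject_errors_impl(bundle, spec, reference_date))
}

inject_errors_impl <- function(bundle, spec, reference_date) {
  ledger <- list()
  note <- function(rule, table, key) {
    ledger[[length(ledger) + 1]] <<- tibble(rule = rule, table = table, key = key)
  }
  need <- function(rule, eligible, n) {
    if (length(eligible) < n) {
      abort(sprintf(
        "rule '%s' requested %d rows but only %d are eligible (shortfall %d)",
        rule, n, length(eligible), n - length(eligible)
      ))
    }
    if (n == 0) character() else sample(eligible, n)
  }

  ind <- bundle$individuals
  taken <- character()

  # future birth dates: birth moved past the reference date
  eligible <- setdiff(ind$individual_id[!is.na(ind$birth_date)], taken)
  targets <- need("future_birth_dates", eligible, spec$future_birth_dates)
  if (length(targets) > 0) {
    i <- match(targets, ind$individual_id)
    ind$birth_date[i] <- reference_date + sample(30:365, length(i), replace = TRUE)
    note("future_birth_dates", "individuals", targets)
    taken <- c(taken, targets)
  }

  # events before birth: birth moved one day past the individual's earliest
  # responded wave, so that wave's events precede birth
  first_wave <- bundle$responses %>%
    dplyr::left_join(bundle$waves[, c("wave_id", "wave_date")], by = "wave_id") %>%
    dplyr::group_by(.data$individual_id) %>%
    dplyr::summarise(first_date = min(.data$wave_date), .groups = "drop")
  eligible <- setdiff(first_wave$individual_id, taken)
  eligible <- eligible[first_wave$first_date[match(eligible, first_wave$individual_id)] + 1 <=
    reference_date]
  targets <- need("event_before_birth", eligible, spec$event_before_birth)
  if (length(targets) > 0) {
    i <- match(targets, ind$individual_id)
    ind$birth_date[i] <- first_wave$first_date[match(targets, first_wave$individual_id)] + 1
    note("event_before_birth", "individuals", targets)
    taken <- c(taken, targets)
  }

  # null required identifiers
  eligible <- setdiff(ind$individual_id[!is.na(ind$individual_id)], taken)
  targets <- need("null_required_ids", eligible, spec$null_required_ids)
  if (length(targets) > 0) {
    ind$individual_id[match(targets, ind$individual_id)] <- NA_character_
    note("null_required_ids", "individuals", targets)
    taken <- c(taken, targets)
  }
  bundle$individuals <- ind

  resp <- bundle$responses
  resp_keys <- response_key(resp$individual_id, resp$wave_id, resp$variable_id)
  vars <- bundle$variables

  # unmapped category codes on non-instrument categorical covariates
  cov_ids <- vars$variable_id[is.na(vars$instrument_id) & vars$value_kind == "categorical"]
  eligible <- which(resp$variable_id %in% cov_ids & !resp$individual_id %in% taken &
    !is.na(resp$individual_id))
  sel <- need("unmapped_codes", eligible, spec$unmapped_codes)
  if (length(sel) > 0) {
    resp$raw_value[sel] <- sprintf("UNK_%03d", seq_along(sel))
    resp$numeric_value[sel] <- NA_real_
    note("unmapped_codes", "responses", resp_keys[sel])
  }

  # out-of-range instrument item values
  item_ids <- vars$variable_id[!is.na(vars$instrument_id)]
  item_max <- purrr::map_dbl(vars$instrument_id, function(ins) {
    if (is.na(ins)) NA_real_ else instrument_definition(ins)$item_max
  })
  max_by_var <- setNames(item_max, vars$variable_id)
  eligible <- setdiff(
    which(resp$variable_id %in% item_ids & !is.na(resp$individual_id) &
      !resp$individual_id %in% taken),
    sel
  )
  sel2 <- need("out_of_range_items", eligible, spec$out_of_range_items)
  if (length(sel2) > 0) {
    bad_val <- max_by_var[resp$variable_id[sel2]] + 5
    resp$raw_value[sel2] <- as.character(bad_val)
    resp$numeric_value[sel2] <- bad_val
    note("out_of_range_items", "responses", resp_keys[sel2])
  }
  bundle$responses <- resp

  ledger <- if (length(ledger) > 0) dplyr::bind_rows(ledger) else empty_ledger()
  list(bundle = bundle, ledger = ledger)
}
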
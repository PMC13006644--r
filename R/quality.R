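#' Define a single data-quality check
#'
#' Declarative description of one row-level rule evaluated against a CDM
#' table: the Kahn category (`Conformance`, `Completeness`, `Plausibility`),
#' the context (`Verification` for CDM-internal rules, `Validation` for rules
#' judged against the vocabulary registry or config-declared external
#' expectations), the table/field scope, a predicate identifier with
#' parameters, and the maximum tolerated violating fraction (0 by default:
#' any violation fails the check).
#'
#' @param check_id Unique check identifier.
#' @param category One of `"Conformance"`, `"Completeness"`, `"Plausibility"`.
#' @param context One of `"Verification"`, `"Validation"`.
#' @param table CDM table name.
#' @param field Field the check targets (may be `NA` for table-level rules).
#' @param rule Predicate identifier (see [run_checks()] for the packaged
#'   rules).
#' @param params Named list of rule parameters.
#' @param threshold Maximum violating fraction in `[0, 1]`.
#' @param description Human-readable account of the rule.
#' @return A one-row tibble.
#' @export
check_definition <- function(check_id, category, context, table, field = NA_character_,
                             rule, params = list(), threshold = 0,
                             description = "") {
  stopifnot(
    category %in% c("Conformance", "Completeness", "Plausibility"),
    context %in% c("Verification", "Validation"),
    threshold >= 0, threshold <= 1
  )
  tibble(
    check_id = check_id, category = category, context = context,
    table = table, field = field, rule = rule, params = list(params),
    threshold = threshold, description = description
  )
}

#' The packaged data-quality check suite
#'
#' A compact, representative suite of row-level checks organised by the Kahn
#' framework — not a re-implementation of the full DQD catalogue. It covers:
#' mandatory-field non-nullity and value presence (Completeness); primary-key
#' uniqueness, foreign-key resolution and date typing (Conformance /
#' Verification); concept resolution, concept-domain agreement,
#' standard-flag conformance and demographic concept membership against the
#' registry (Conformance / Validation); temporal consistency — event date not
#' before birth, not after the reference date, visit start not after end —
#' and birth-year sanity (Plausibility / Verification); and instrument score
#' and item ranges declared by the instrument definitions (Plausibility /
#' Validation). Thresholds default to 0 throughout.
#'
#' @param registry Optional `concept_registry`; registry-backed Validation
#'   checks are only generated when it is supplied.
#' @param plan Optional `mapping_plan`; instrument range checks are generated
#'   from its score and entry maps when supplied.
#' @param variables Optional staging variables table (needed alongside `plan`
#'   to tie item concepts to instruments).
#' @param defns Instrument definitions, default [instrument_definitions()].
#' @param config An [etl_config()] (supplies the reference date).
#' @return A check-definition tibble with at least 30 rows.
#' @export
default_check_suite <- function(registry = NULL, plan = NULL, variables = NULL,
                                defns = instrument_definitions(),
                                config = etl_config()) {
  cks <- list()
  add <- function(...) cks[[length(cks) + 1]] <<- check_definition(...)

  ## Completeness / Verification: mandatory fields
  mandatory <- list(
    location = "location_id",
    person = c("person_id", "gender_concept_id", "year_of_birth"),
    visit_occurrence = c("visit_occurrence_id", "person_id", "visit_concept_id",
      "visit_start_date", "visit_end_date"),
    measurement = c("measurement_id", "person_id", "measurement_concept_id",
      "measurement_date"),
    observation = c("observation_id", "person_id", "observation_concept_id",
      "observation_date"),
    condition_occurrence = c("condition_occurrence_id", "person_id",
      "condition_concept_id", "condition_start_date")
  )
  for (tbl in names(mandatory)) {
    for (fld in mandatory[[tbl]]) {
      add(sprintf("complete_%s_%s", tbl, fld), "Completeness", "Verification",
        tbl, fld, "not_null",
        description = sprintf("%s.%s is never null", tbl, fld))
    }
  }
  add("complete_measurement_value", "Completeness", "Verification",
    "measurement", NA, "any_value_present",
    params = list(fields = c("value_as_number", "value_as_concept_id")),
    description = "every measurement carries a numeric or concept value")
  add("complete_observation_value", "Completeness", "Verification",
    "observation", NA, "any_value_present",
    params = list(fields = c("value_as_number", "value_as_concept_id",
      "value_as_string")),
    description = "every observation carries a value")

  ## Conformance / Verification: keys, foreign keys, typing
  pks <- c(location = "location_id", person = "person_id",
    visit_occurrence = "visit_occurrence_id", measurement = "measurement_id",
    observation = "observation_id",
    condition_occurrence = "condition_occurrence_id")
  for (tbl in names(pks)) {
    add(sprintf("unique_%s", pks[[tbl]]), "Conformance", "Verification",
      tbl, pks[[tbl]], "unique_key",
      description = sprintf("%s is unique within %s", pks[[tbl]], tbl))
  }
  fks <- list(
    c("person", "location_id", "location", "location_id"),
    c("visit_occurrence", "person_id", "person", "person_id"),
    c("measurement", "person_id", "person", "person_id"),
    c("measurement", "visit_occurrence_id", "visit_occurrence", "visit_occurrence_id"),
    c("observation", "person_id", "person", "person_id"),
    c("observation", "visit_occurrence_id", "visit_occurrence", "visit_occurrence_id"),
    c("condition_occurrence", "person_id", "person", "person_id"),
    c("condition_occurrence", "visit_occurrence_id", "visit_occurrence",
      "visit_occurrence_id")
  )
  for (fk in fks) {
    add(sprintf("fk_%s_%s", fk[1], fk[2]), "Conformance", "Verification",
      fk[1], fk[2], "foreign_key",
      params = list(parent_table = fk[3], parent_field = fk[4]),
      description = sprintf("%s.%s resolves in %s", fk[1], fk[2], fk[3]))
  }
  for (spec in list(c("visit_occurrence", "visit_start_date"),
    c("measurement", "measurement_date"), c("observation", "observation_date"),
    c("condition_occurrence", "condition_start_date"))) {
    add(sprintf("type_%s_%s", spec[1], spec[2]), "Conformance", "Verification",
      spec[1], spec[2], "is_date",
      description = sprintf("%s.%s is a calendar date", spec[1], spec[2]))
  }

  ## Conformance / Validation: registry-backed semantic checks
  if (!is.null(registry)) {
    event_concepts <- list(
      c("measurement", "measurement_concept_id", "Measurement"),
      c("observation", "observation_concept_id", "Observation"),
      c("condition_occurrence", "condition_concept_id", "Condition")
    )
    for (ec in event_concepts) {
      add(sprintf("resolve_%s_%s", ec[1], ec[2]), "Conformance", "Validation",
        ec[1], ec[2], "concept_resolves",
        description = sprintf("%s.%s exists in the vocabulary", ec[1], ec[2]))
      add(sprintf("domain_%s_%s", ec[1], ec[2]), "Conformance", "Validation",
        ec[1], ec[2], "concept_in_domain", params = list(domain = ec[3]),
        description = sprintf("%s.%s belongs to the %s domain", ec[1], ec[2], ec[3]))
      add(sprintf("standard_%s_%s", ec[1], ec[2]), "Conformance", "Validation",
        ec[1], ec[2], "concept_is_standard",
        description = sprintf("%s.%s is standard-flagged", ec[1], ec[2]))
    }
    demo_concepts <- list(
      c("person", "gender_concept_id", "Gender"),
      c("person", "race_concept_id", "Race"),
      c("person", "ethnicity_concept_id", "Ethnicity")
    )
    for (dc in demo_concepts) {
      add(sprintf("member_%s_%s", dc[1], dc[2]), "Conformance", "Validation",
        dc[1], dc[2], "concept_in_domain",
        params = list(domain = dc[3], allow_zero = TRUE),
        description = sprintf("%s.%s is a %s concept (0 allowed for unknown)",
          dc[1], dc[2], dc[3]))
    }
  }

  ## Plausibility / Verification: temporal consistency
  add("visit_start_le_end", "Plausibility", "Verification", "visit_occurrence",
    NA, "start_le_end",
    params = list(start = "visit_start_date", end = "visit_end_date"),
    description = "visit start date is not after visit end date")
  for (spec in list(c("visit_occurrence", "visit_start_date"),
    c("measurement", "measurement_date"), c("observation", "observation_date"),
    c("condition_occurrence", "condition_start_date"))) {
    add(sprintf("after_birth_%s", spec[1]), "Plausibility", "Verification",
      spec[1], spec[2], "event_after_birth", params = list(date = spec[2]),
      description = sprintf("%s.%s is not before the person's birth", spec[1], spec[2]))
    add(sprintf("before_reference_%s", spec[1]), "Plausibility", "Verification",
      spec[1], spec[2], "date_le_reference",
      params = list(date = spec[2], reference_date = config$reference_date),
      description = sprintf("%s.%s is not after the reference date", spec[1], spec[2]))
  }
  add("birth_year_sane", "Plausibility", "Verification", "person",
    "year_of_birth", "value_range",
    params = list(field = "year_of_birth", min = 1900,
      max = as.integer(format(config$reference_date, "%Y"))),
    description = "year of birth lies between 1900 and the reference year")

  ## Plausibility / Validation: instrument ranges from the definitions
  if (!is.null(plan) && !is.null(variables)) {
    for (i in seq_len(nrow(plan$score_map))) {
      ins <- plan$score_map$instrument_id[i]
      d <- try(instrument_definition(ins, defns), silent = TRUE)
      if (inherits(d, "try-error")) next
      mult <- if (d$score_rule == "sum_times_two") 2 else 1
      add(sprintf("score_range_%s", instrument_slug(ins)), "Plausibility",
        "Validation", "measurement", "value_as_number", "value_range_for_concepts",
        params = list(concept_ids = plan$score_map$concept_id[i],
          field = "value_as_number",
          min = mult * d$n_items * d$item_min, max = mult * d$n_items * d$item_max),
        description = sprintf("%s total score within its published range", ins))
      item_ids <- variables$variable_id[!is.na(variables$instrument_id) &
        variables$instrument_id == ins]
      item_concepts <- plan$entries$target_concept_id[
        plan$entries$variable_id %in% item_ids]
      if (length(item_concepts) > 0) {
        add(sprintf("item_range_%s", instrument_slug(ins)), "Plausibility",
          "Validation", "observation", "value_as_number", "value_range_for_concepts",
          params = list(concept_ids = item_concepts, field = "value_as_number",
            min = d$item_min, max = d$item_max),
          description = sprintf("%s item responses within their response range", ins))
      }
    }
  }

  dplyr::bind_rows(cks)
}

# --- predicate engine -------------------------------------------------------

check_rules <- function() {
  list(
    not_null = function(tbl, def, env) {
      x <- tbl[[def$field]]
      list(eval = rep(TRUE, nrow(tbl)), viol = is.na(x))
    },
    any_value_present = function(tbl, def, env) {
      fields <- def$params[[1]]$fields
      present <- Reduce(`|`, lapply(fields, function(f) !is.na(tbl[[f]])))
      list(eval = rep(TRUE, nrow(tbl)), viol = !present)
    },
    unique_key = function(tbl, def, env) {
      x <- tbl[[def$field]]
      list(eval = rep(TRUE, nrow(tbl)), viol = duplicated(x) | duplicated(x, fromLast = TRUE))
    },
    foreign_key = function(tbl, def, env) {
      p <- def$params[[1]]
      parent <- env$cdm$tables[[p$parent_table]][[p$parent_field]]
      x <- tbl[[def$field]]
      list(eval = !is.na(x), viol = !is.na(x) & !x %in% parent)
    },
    is_date = function(tbl, def, env) {
      x <- tbl[[def$field]]
      list(eval = rep(TRUE, nrow(tbl)), viol = !inherits(x, "Date") | is.na(x))
    },
    concept_resolves = function(tbl, def, env) {
      x <- tbl[[def$field]]
      list(eval = !is.na(x), viol = !is.na(x) & !x %in% env$registry$concepts$concept_id)
    },
    concept_in_domain = function(tbl, def, env) {
      p <- def$params[[1]]
      ok_ids <- env$registry$concepts$concept_id[
        env$registry$concepts$domain_id == p$domain]
      if (isTRUE(p$allow_zero)) ok_ids <- c(0, ok_ids)
      x <- tbl[[def$field]]
      list(eval = !is.na(x), viol = !is.na(x) & !x %in% ok_ids)
    },
    concept_is_standard = function(tbl, def, env) {
      std <- env$registry$concepts$concept_id[
        !is.na(env$registry$concepts$standard_concept) &
          env$registry$concepts$standard_concept == "S"]
      x <- tbl[[def$field]]
      list(eval = !is.na(x), viol = !is.na(x) & !x %in% std)
    },
    start_le_end = function(tbl, def, env) {
      p <- def$params[[1]]
      s <- tbl[[p$start]]; e <- tbl[[p$end]]
      eval <- !is.na(s) & !is.na(e)
      list(eval = eval, viol = eval & s > e)
    },
    event_after_birth = function(tbl, def, env) {
      p <- def$params[[1]]
      person <- env$cdm$tables$person
      i <- match(tbl$person_id, person$person_id)
      birth <- as.Date(sprintf("%04d-%02d-%02d", person$year_of_birth[i],
        dplyr::coalesce(person$month_of_birth[i], 7L),
        dplyr::coalesce(person$day_of_birth[i], 1L)))
      d <- tbl[[p$date]]
      eval <- !is.na(d) & !is.na(birth)
      list(eval = eval, viol = eval & d < birth)
    },
    date_le_reference = function(tbl, def, env) {
      p <- def$params[[1]]
      d <- tbl[[p$date]]
      eval <- !is.na(d)
      list(eval = eval, viol = eval & d > as_iso_date(p$reference_date))
    },
    value_range = function(tbl, def, env) {
      p <- def$params[[1]]
      x <- tbl[[p$field]]
      eval <- !is.na(x)
      list(eval = eval, viol = eval & (x < p$min | x > p$max))
    },
    value_range_for_concepts = function(tbl, def, env) {
      p <- def$params[[1]]
      concept_col <- grep("_concept_id$", names(tbl), value = TRUE)[1]
      in_set <- tbl[[concept_col]] %in% p$concept_ids
      x <- tbl[[p$field]]
      eval <- in_set & !is.na(x)
      list(eval = eval, viol = eval & (x < p$min | x > p$max))
    }
  )
}

#' Run a quality-check suite against a CDM bundle
#'
#' Evaluates every applicable check deterministically and rolls the outcomes
#' up Kahn-style. A check passes when its violating fraction does not exceed
#' its threshold; a check whose table has no evaluable rows is
#' `NOT_APPLICABLE` and excluded from pass-rate denominators. Violating row
#' keys (the table's source-value column where available) are retained per
#' check so that findings can be reconciled against an injection ledger.
#'
#' @param cdm A `cdm_bundle`.
#' @param registry The `concept_registry` used for Validation checks.
#' @param suite A check-definition tibble, e.g. [default_check_suite()].
#' @return A `qc_report`: `results` (one row per check, with a
#'   `violating_keys` list-column) and `rollup` (see [summarize_report()]).
#' @export
run_checks <- function(cdm, registry = NULL, suite = default_check_suite(registry)) {
  bad_tbl <- setdiff(unique(suite$table), names(cdm$tables))
  if (length(bad_tbl) > 0) {
    abort(sprintf("check suite references unknown table(s): %s",
      paste(bad_tbl, collapse = ", ")))
  }
  rules <- check_rules()
  bad_rule <- setdiff(unique(suite$rule), names(rules))
  if (length(bad_rule) > 0) {
    abort(sprintf("unknown check rule(s): %s", paste(bad_rule, collapse = ", ")))
  }
  env <- list(cdm = cdm, registry = registry)

  results <- purrr::map(seq_len(nrow(suite)), function(i) {
    def <- suite[i, ]
    tbl <- cdm$tables[[def$table]]
    res <- rules[[def$rule]](tbl, def, env)
    n_eval <- sum(res$eval)
    n_viol <- sum(res$viol)
    status <- if (n_eval == 0) "NOT_APPLICABLE" else if (n_viol / n_eval <= def$threshold) "PASS" else "FAIL"
    key_col <- grep("_source_value$", names(tbl), value = TRUE)[1]
    keys <- if (!is.na(key_col)) tbl[[key_col]][res$viol] else
      as.character(which(res$viol))
    tibble(
      check_id = def$check_id, category = def$category, context = def$context,
      table = def$table, field = def$field,
      rows_evaluated = as.integer(n_eval), rows_violating = as.integer(n_viol),
      violation_fraction = if (n_eval == 0) NA_real_ else n_viol / n_eval,
      threshold = def$threshold, status = status,
      violating_keys = list(keys)
    )
  }) %>% dplyr::bind_rows()

  report <- structure(
    list(results = results, rollup = NULL, n_checks = nrow(results)),
    class = "qc_report"
  )
  report$rollup <- summarize_report(report)
  report
}

#' Roll a quality report up by Kahn category and context
#'
#' Produces the classic pass/fail rollup: one row per category
#' (Plausibility, Conformance, Completeness, plus Total) crossed with
#' Verification, Validation and Total contexts, each carrying pass, fail and
#' total counts and the pass percentage rounded to a whole percent.
#' `NOT_APPLICABLE` results are excluded from all denominators; cells with no
#' checks have an undefined pass rate (`NA`, rendered blank).
#'
#' @param report A `qc_report`.
#' @return A tibble `category`, `context`, `pass`, `fail`, `total`,
#'   `pct_pass`.
#' @export
summarize_report <- function(report) {
  res <- report$results
  res <- res[res$status != "NOT_APPLICABLE", ]
  cats <- c("Plausibility", "Conformance", "Completeness", "Total")
  ctxs <- c("Verification", "Validation", "Total")
  grid <- tidyr::expand_grid(category = cats, context = ctxs)
  purrr::pmap(grid, function(category, context) {
    sel <- res
    if (category != "Total") sel <- sel[sel$category == category, ]
    if (context != "Total") sel <- sel[sel$context == context, ]
    pass <- sum(sel$status == "PASS"); fail <- sum(sel$status == "FAIL")
    tibble(
      category = category, context = context, pass = pass, fail = fail,
      total = pass + fail,
      pct_pass = if (pass + fail == 0) NA_real_ else round(100 * pass / (pass + fail))
    )
  }) %>% dplyr::bind_rows()
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$n_checks, "checks\n")
  roll <- x$rollup
  roll$pct_pass <- ifelse(is.na(roll$pct_pass), "", paste0(roll$pct_pass, "%"))
  print(as.data.frame(roll), row.names = FALSE)
  invisible(x)
}

#' Reconcile injected errors against ETL cleaning and QC detection
#'
#' Every deliberately injected corruption must be accounted for: either the
#' ETL cleaned it (nulled / excluded / remapped it, leaving an error-log entry
#' whose rule names the injection) or the quality checks detected it in the
#' CDM. Because a single corrupted source cell (e.g. one shifted birth date)
#' can cascade into several downstream log rows, accounting is at the level
#' of the injected source key: a ledger entry is *accounted* when at least
#' one ETL-log entry or QC violating key traces back to it. Per rule,
#' `accounted == injected` means nothing slipped through.
#'
#' @param ledger Injection ledger from [inject_errors()].
#' @param cdm The `cdm_bundle` produced from the corrupted bundle.
#' @param report The `qc_report` computed on that bundle.
#' @return A tibble: `rule`, `injected`, `cleaned_by_etl`, `detected_by_qc`,
#'   `accounted`.
#' @export
reconcile_injections <- function(ledger, cdm, report) {
  log <- cdm$error_log
  qc_keys <- unique(unlist(report$results$violating_keys))
  # ETL log keys that contain a source key (individual ids or response keys)
  rule_match <- c(
    future_birth_dates = "future_birth_date",
    event_before_birth = "event_before_birth",
    null_required_ids = "null_person_id",
    unmapped_codes = "unmapped_code",
    out_of_range_items = "out_of_range_item"
  )
  rules <- unique(ledger$rule)
  purrr::map(rules, function(rule) {
    keys <- ledger$key[ledger$rule == rule]
    etl_rule <- unname(rule_match[rule])
    log_keys <- log$row_key[!is.na(log$rule) & log$rule %in% etl_rule]
    cleaned <- vapply(keys, function(k) {
      any(log_keys == k) || any(startsWith(log_keys, paste0(k, "::")))
    }, logical(1))
    if (rule == "null_required_ids") {
      # the id itself is gone; count the null-id exclusions positionally
      n_null <- sum(log$rule == "null_person_id", na.rm = TRUE)
      cleaned <- rep(FALSE, length(keys))
      cleaned[seq_len(min(n_null, length(keys)))] <- TRUE
    }
    detected <- vapply(keys, function(k) {
      any(qc_keys == k, na.rm = TRUE) ||
        any(startsWith(qc_keys[!is.na(qc_keys)], paste0(k, "::")))
    }, logical(1))
    tibble(
      rule = rule, injected = length(keys),
      cleaned_by_etl = sum(cleaned), detected_by_qc = sum(detected),
      accounted = sum(cleaned | detected)
    )
  }) %>% dplyr::bind_rows()
}
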
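#' Route a staging variable to its target OMOP domain
#'
#' Total routing function over the variables table: quantitative variables
#' with a defined unit or scale go to `Measurement`; variables flagged as
#' diagnoses go to `Condition` (the flag must be explicit in the variable
#' metadata); everything else — categorical questionnaire content, symptom
#' presence, free text — goes to `Observation`.
#'
#' @param variables Staging variables tibble (see [staging_bundle()]).
#' @return The input with a `target_domain` column appended.
#' @export
route_domain <- function(variables) {
  assert_columns(variables, c("variable_id", "value_kind"), "variables")
  is_diag <- variables$is_diagnosis %||% rep(FALSE, nrow(variables))
  is_diag[is.na(is_diag)] <- FALSE
  unit <- variables$unit_label %||% rep(NA_character_, nrow(variables))
  domain <- dplyr::case_when(
    is_diag ~ "Condition",
    variables$value_kind == "quantitative" & !is.na(unit) ~ "Measurement",
    TRUE ~ "Observation"
  )
  dplyr::mutate(variables, target_domain = domain)
}

mapping_table_cols <- function() {
  readr::cols(
    variable_id = "c", target_concept_id = "d", target_domain = "c",
    value_label = "c", value_concept_id = "d", unit_concept_id = "d"
  )
}

#' Read / write a curated mapping table
#'
#' The mapping table is an explicit input artifact (mappings are created by
#' expert review, not guessed): comma-separated with columns `variable_id`,
#' `target_concept_id`, `target_domain`, `value_label`, `value_concept_id`,
#' `unit_concept_id`. A variable's base row has an empty `value_label`;
#' additional rows per category label define the value map.
#'
#' @param path File path.
#' @return A tibble (for `read_mapping_table`); the path, invisibly (for
#'   `write_mapping_table`).
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing mapping table: %s", path))
  readr::read_csv(path, col_types = mapping_table_cols(), na = "", progress = FALSE)
}

#' @rdname read_mapping_table
#' @param mapping_table Tibble in the mapping-table layout.
#' @export
write_mapping_table <- function(mapping_table, path) {
  readr::write_csv(mapping_table, path, na = "", progress = FALSE)
  invisible(path)
}

#' Compile a study-level mapping plan
#'
#' Takes one mapping decision per distinct staging variable: a resolvable
#' curated mapping yields a plan entry; anything else is routed to the review
#' queue with a reason (`no_equivalent` for absent or unresolvable concepts,
#' `deprecated` for concepts whose validity has ended). No variable is ever
#' silently dropped: entries plus deduplicated review rows always partition
#' the variable set. Coverage is the mapped fraction; an empty study has
#' coverage 1 by definition (documented vacuous case).
#'
#' @param bundle A `staging_bundle`.
#' @param registry A `concept_registry`.
#' @param mapping_table Curated mapping tibble (see [read_mapping_table()]).
#' @param reference_date Date against which concept validity is judged;
#'   defaults to the bundle's latest wave date.
#' @param auto_match If `TRUE`, variables absent from the table are matched by
#'   exact concept name as a convenience; off by default.
#' @return An object of class `mapping_plan`: `entries`, `value_map`,
#'   `review_queue`, `coverage`, `n_variables`.
#' @export
compile_mapping_plan <- function(bundle, registry, mapping_table,
                                 reference_date = NULL, auto_match = FALSE) {
  vars <- route_domain(bundle$variables)
  if (is.null(reference_date)) {
    reference_date <- if (nrow(bundle$waves) > 0) max(bundle$waves$wave_date)
      else as.Date("2099-12-31")
  }
  reference_date <- as_iso_date(reference_date)
  concepts <- registry$concepts

  entries <- list(); value_map <- list(); review <- list()
  for (i in seq_len(nrow(vars))) {
    vid <- vars$variable_id[i]
    rows <- mapping_table[mapping_table$variable_id == vid, ]
    base <- rows[is.na(rows$value_label), ]
    target <- if (nrow(base) > 0) base$target_concept_id[1] else NA_real_

    if (is.na(target) && auto_match) {
      hit <- concepts[concepts$concept_name == vid, ]
      if (nrow(hit) == 1) target <- hit$concept_id
    }
    if (is.na(target)) {
      review[[length(review) + 1]] <- tibble(variable_id = vid, reason = "no_equivalent")
      next
    }
    ci <- match(target, concepts$concept_id)
    if (is.na(ci)) {
      review[[length(review) + 1]] <- tibble(variable_id = vid, reason = "no_equivalent")
      next
    }
    deprecated <- !is.na(concepts$invalid_reason[ci]) ||
      concepts$valid_end_date[ci] < reference_date
    if (deprecated) {
      review[[length(review) + 1]] <- tibble(variable_id = vid, reason = "deprecated")
      next
    }
    vrows <- rows[!is.na(rows$value_label), ]
    if (nrow(vrows) > 0 && !all(vrows$value_concept_id %in% concepts$concept_id)) {
      review[[length(review) + 1]] <- tibble(variable_id = vid, reason = "no_equivalent")
      next
    }
    domain <- if (nrow(base) > 0 && !is.na(base$target_domain[1])) base$target_domain[1]
      else vars$target_domain[i]
    entries[[length(entries) + 1]] <- tibble(
      variable_id = vid, target_concept_id = target, target_domain = domain,
      unit_concept_id = if (nrow(base) > 0) base$unit_concept_id[1] else NA_real_
    )
    if (nrow(vrows) > 0) {
      value_map[[length(value_map) + 1]] <- vrows[, c("variable_id", "value_label",
        "value_concept_id")]
    }
  }

  entries <- if (length(entries) > 0) dplyr::bind_rows(entries) else
    tibble(variable_id = character(), target_concept_id = numeric(),
      target_domain = character(), unit_concept_id = numeric())
  value_map <- if (length(value_map) > 0) dplyr::bind_rows(value_map) else
    tibble(variable_id = character(), value_label = character(),
      value_concept_id = numeric())
  review <- if (length(review) > 0) dplyr::bind_rows(review) else
    tibble(variable_id = character(), reason = character())

  # composite-score pseudo-variables ("<instrument>__total") ride along in the
  # mapping table but are not staging variables; they do not enter coverage
  tot_rows <- mapping_table[grepl("__total$", mapping_table$variable_id) &
    is.na(mapping_table$value_label), ]
  score_map <- tibble(
    instrument_id = sub("__total$", "", tot_rows$variable_id),
    concept_id = tot_rows$target_concept_id,
    unit_concept_id = tot_rows$unit_concept_id
  )
  score_map <- score_map[score_map$concept_id %in% concepts$concept_id, ]

  n_vars <- dplyr::n_distinct(vars$variable_id)
  coverage <- if (n_vars == 0) 1 else nrow(entries) / n_vars
  structure(
    list(
      entries = entries, value_map = value_map, review_queue = review,
      score_map = score_map, coverage = coverage, n_variables = n_vars
    ),
    class = "mapping_plan"
  )
}

#' @export
print.mapping_plan <- function(x, ...) {
  cat(sprintf(
    "<mapping_plan> %d/%d variables mapped (coverage %.1f%%), %d in review queue\n",
    nrow(x$entries), x$n_variables, 100 * x$coverage, nrow(x$review_queue)
  ))
  invisible(x)
}

# Pseudo-variable key under which an instrument's composite-score concept is
# carried in the mapping table (composites are derived, not staged).
total_score_key <- function(instrument_id) paste0(instrument_id, "__total")

#' Base standard concepts used by the synthetic studies
#'
#' A compact set of well-known OMOP standard concepts (gender, race,
#' ethnicity, survey type, home-visit, screening-positive condition concepts,
#' and the `0` "No matching concept" sentinel) sufficient to run the pipeline
#' end to end on synthetic data.
#'
#' @return A concepts tibble suitable for [register_concepts()].
#' @export
base_standard_concepts <- function() {
  tibble(
    concept_id = c(0, 8532, 8507, 8516, 8527, 38003563, 38003564,
      32862, 581476, 440383, 442077, 4086911),
    concept_name = c(
      "No matching concept", "FEMALE", "MALE", "Black or African American",
      "White", "Hispanic or Latino", "Not Hispanic or Latino",
      "Patient filled survey", "Home Visit", "Depressive disorder",
      "Anxiety disorder", "Marital status"
    ),
    domain_id = c(
      "Metadata", "Gender", "Gender", "Race", "Race", "Ethnicity", "Ethnicity",
      "Type Concept", "Visit", "Condition", "Condition", "Observation"
    ),
    vocabulary_id = c(
      "None", "Gender", "Gender", "Race", "Race", "Ethnicity", "Ethnicity",
      "Type Concept", "Visit", "SNOMED", "SNOMED", "SNOMED"
    )
  )
}

#' Build the vocabulary and mapping table for a (synthetic) study
#'
#' Mints one local Observation concept per staging variable, one local
#' `Meas Value` answer concept per category of each categorical covariate
#' (paired to its question with `Has answer` / `Is an answer of`
#' relationships), and one local Measurement concept per administered
#' instrument's composite score; registers the base standard concepts; and
#' compiles the curated mapping table that ties variables (and composite
#' pseudo-variables) to those concepts. This mirrors the expert-review mapping
#' step for data whose ground truth is known.
#'
#' @param bundle A `staging_bundle`.
#' @param registry Optionally, an existing `concept_registry` to extend;
#'   defaults to a fresh registry seeded with [base_standard_concepts()].
#' @return A list: `registry` (a `concept_registry`) and `mapping` (a mapping
#'   table tibble).
#' @export
build_study_vocabulary <- function(bundle, registry = NULL) {
  if (is.null(registry)) {
    registry <- register_concepts(concept_registry(), base_standard_concepts())
  }
  vars <- route_domain(bundle$variables)
  mapping <- list()

  # one local concept per staging variable
  if (nrow(vars) > 0) {
    registry <- mint_local_concepts(registry, tibble(
      name = vars$variable_id,
      domain_id = ifelse(vars$target_domain == "Condition", "Condition",
        "Observation")
    ))
    var_concepts <- minted_concepts(registry)
    mapping[[length(mapping) + 1]] <- tibble(
      variable_id = vars$variable_id,
      target_concept_id = var_concepts$concept_id,
      target_domain = vars$target_domain,
      value_label = NA_character_, value_concept_id = NA_real_,
      unit_concept_id = NA_real_
    )

    # answer concepts for categorical covariates (non-numeric categories)
    cov <- vars[is.na(vars$instrument_id) & vars$value_kind == "categorical", ]
    for (i in seq_len(nrow(cov))) {
      labels <- strsplit(cov$allowed_values[i], "\\|")[[1]]
      if (all(!is.na(suppressWarnings(as.numeric(labels))))) next
      registry <- mint_local_concepts(registry, tibble(
        name = paste0(cov$variable_id[i], ": ", labels),
        domain_id = "Meas Value"
      ))
      ans <- minted_concepts(registry)
      q_id <- var_concepts$concept_id[match(cov$variable_id[i], vars$variable_id)]
      for (j in seq_len(nrow(ans))) {
        registry <- pair_relationship(registry, q_id, ans$concept_id[j], "Has answer")
      }
      mapping[[length(mapping) + 1]] <- tibble(
        variable_id = cov$variable_id[i],
        target_concept_id = q_id, target_domain = "Observation",
        value_label = labels, value_concept_id = ans$concept_id,
        unit_concept_id = NA_real_
      )
    }
  }

  # composite-score concepts per administered instrument
  instruments <- unique(stats::na.omit(vars$instrument_id))
  if (length(instruments) > 0) {
    registry <- mint_local_concepts(registry, tibble(
      name = paste(instruments, "total score"),
      domain_id = "Measurement"
    ))
    tot <- minted_concepts(registry)
    mapping[[length(mapping) + 1]] <- tibble(
      variable_id = total_score_key(instruments),
      target_concept_id = tot$concept_id, target_domain = "Measurement",
      value_label = NA_character_, value_concept_id = NA_real_,
      unit_concept_id = NA_real_
    )
  }

  mapping <- if (length(mapping) > 0) dplyr::bind_rows(mapping) else
    tibble(variable_id = character(), target_concept_id = numeric(),
      target_domain = character(), value_label = character(),
      value_concept_id = numeric(), unit_concept_id = numeric())
  list(registry = registry, mapping = mapping)
}
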
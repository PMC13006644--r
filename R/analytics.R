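#' Define a cohort
#'
#' A cohort entry criterion: a CDM event domain, a non-empty concept set, an
#' optional value predicate on `value_as_number` (so screening-score cohorts
#' like "PHQ-9 total >= 10" can be expressed directly against Measurement),
#' and the entry restriction. Under `earliest_event_only` (the default) each
#' person contributes at most one membership, indexed at their first
#' qualifying event, making persons and episodes one-to-one.
#'
#' @param cohort_id Cohort label.
#' @param domain One of `"condition_occurrence"`, `"measurement"`,
#'   `"observation"`.
#' @param concept_ids Non-empty numeric vector of event concept ids.
#' @param value_min,value_max Optional bounds on `value_as_number`.
#' @param restriction `"earliest_event_only"` or `"all_events"`.
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(cohort_id, domain, concept_ids,
                              value_min = NULL, value_max = NULL,
                              restriction = c("earliest_event_only", "all_events")) {
  restriction <- match.arg(restriction)
  if (length(concept_ids) == 0) abort("cohort concept set must be non-empty")
  domain <- match.arg(domain, c("condition_occurrence", "measurement", "observation"))
  structure(
    list(cohort_id = cohort_id, domain = domain,
      concept_ids = as.numeric(concept_ids),
      value_min = value_min, value_max = value_max, restriction = restriction),
    class = "cohort_definition"
  )
}

domain_event_cols <- function() {
  list(
    condition_occurrence = c(id = "condition_occurrence_id",
      concept = "condition_concept_id", date = "condition_start_date"),
    measurement = c(id = "measurement_id", concept = "measurement_concept_id",
      date = "measurement_date"),
    observation = c(id = "observation_id", concept = "observation_concept_id",
      date = "observation_date")
  )
}

# All qualifying events for a definition: person_id, event_date, record_id.
cohort_events <- function(cdm, defn) {
  cols <- domain_event_cols()[[defn$domain]]
  tbl <- cdm$tables[[defn$domain]]
  keep <- tbl[[cols[["concept"]]]] %in% defn$concept_ids
  if (!is.null(defn$value_min)) {
    keep <- keep & !is.na(tbl$value_as_number) & tbl$value_as_number >= defn$value_min
  }
  if (!is.null(defn$value_max)) {
    keep <- keep & !is.na(tbl$value_as_number) & tbl$value_as_number <= defn$value_max
  }
  keep <- keep & !is.na(tbl[[cols[["date"]]]])
  tibble(
    person_id = tbl$person_id[keep],
    event_date = tbl[[cols[["date"]]]][keep],
    record_id = tbl[[cols[["id"]]]][keep]
  )
}

#' Build cohort memberships
#'
#' Under `earliest_event_only`, each person's membership is indexed at their
#' earliest qualifying event; a same-date tie is broken deterministically
#' toward the smallest record identifier (the date, and hence the
#' membership, is unaffected). Under `all_events` every qualifying event
#' becomes a row.
#'
#' @param cdm A `cdm_bundle`.
#' @param defn A [cohort_definition()].
#' @return Tibble `cohort_id`, `person_id`, `index_date` (and `record_id`).
#' @export
build_cohort <- function(cdm, defn) {
  events <- cohort_events(cdm, defn)
  if (defn$restriction == "earliest_event_only" && nrow(events) > 0) {
    events <- events %>%
      dplyr::arrange(.data$person_id, .data$event_date, .data$record_id) %>%
      dplyr::distinct(.data$person_id, .keep_all = TRUE)
  }
  tibble(
    cohort_id = rep(defn$cohort_id, nrow(events)),
    person_id = events$person_id,
    index_date = events$event_date,
    record_id = events$record_id
  )
}

person_birth_dates <- function(person) {
  as.Date(sprintf("%04d-%02d-%02d", person$year_of_birth,
    dplyr::coalesce(person$month_of_birth, 7L),
    dplyr::coalesce(person$day_of_birth, 1L)))
}

# Observation window surrogate: each person's first and last recorded event
# date across the event tables (visits included).
observation_window <- function(cdm) {
  evs <- dplyr::bind_rows(
    tibble(person_id = cdm$tables$visit_occurrence$person_id,
      d = cdm$tables$visit_occurrence$visit_start_date),
    tibble(person_id = cdm$tables$measurement$person_id,
      d = cdm$tables$measurement$measurement_date),
    tibble(person_id = cdm$tables$observation$person_id,
      d = cdm$tables$observation$observation_date),
    tibble(person_id = cdm$tables$condition_occurrence$person_id,
      d = cdm$tables$condition_occurrence$condition_start_date)
  )
  evs %>%
    dplyr::filter(!is.na(.data$d)) %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::summarise(obs_start = min(.data$d), obs_end = max(.data$d),
      .groups = "drop")
}

#' Describe a cohort's composition
#'
#' Univariate descriptive statistics at cohort entry. Categorical features
#' (index year, gender, 10-year age group, race, ethnicity) yield counts and
#' proportions that sum to one within a feature; continuous features (age at
#' index, prior/post observation days) yield mean, sd and median rows in the
#' `value` column. Age uses year (and month/day where present) of birth;
#' missing month/day is taken as July 1.
#'
#' @param cdm A `cdm_bundle`.
#' @param memberships Cohort memberships from [build_cohort()].
#' @param features Which features to compute.
#' @return Tibble `feature`, `level`, `n`, `proportion`, `value`.
#' @export
characterize_cohort <- function(cdm, memberships,
                                features = c("index_year", "gender", "age",
                                  "age_group", "race", "ethnicity",
                                  "prior_observation", "post_observation")) {
  if (nrow(memberships) == 0) {
    return(tibble(feature = character(), level = character(), n = integer(),
      proportion = numeric(), value = numeric()))
  }
  person <- cdm$tables$person
  i <- match(memberships$person_id, person$person_id)
  birth <- person_birth_dates(person)[i]
  age <- as.numeric(memberships$index_date - birth) / 365.25
  win <- observation_window(cdm)
  wi <- match(memberships$person_id, win$person_id)
  prior <- as.numeric(memberships$index_date - win$obs_start[wi])
  post <- as.numeric(win$obs_end[wi] - memberships$index_date)

  concept_label <- function(ids, map) {
    lab <- names(map)[match(ids, map)]
    ifelse(is.na(lab), paste0("concept_", format(ids, scientific = FALSE)), lab)
  }
  gender_lab <- concept_label(person$gender_concept_id[i],
    c(female = 8532, male = 8507, unknown = 0))
  race_lab <- concept_label(person$race_concept_id[i],
    c(black = 8516, white = 8527, unknown = 0))
  eth_lab <- concept_label(person$ethnicity_concept_id[i],
    c(hispanic = 38003563, not_hispanic = 38003564, unknown = 0))

  categorical <- function(feature, lev) {
    tab <- table(lev, useNA = "no")
    tibble(feature = feature, level = names(tab), n = as.integer(tab),
      proportion = as.numeric(tab) / sum(tab), value = NA_real_)
  }
  continuous <- function(feature, x) {
    tibble(
      feature = feature, level = c("mean", "sd", "median"),
      n = rep(sum(!is.na(x)), 3), proportion = NA_real_,
      value = c(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE),
        stats::median(x, na.rm = TRUE))
    )
  }

  out <- list()
  if ("index_year" %in% features) {
    out[[length(out) + 1]] <- categorical("index_year",
      format(memberships$index_date, "%Y"))
  }
  if ("gender" %in% features) out[[length(out) + 1]] <- categorical("gender", gender_lab)
  if ("age" %in% features) out[[length(out) + 1]] <- continuous("age", age)
  if ("age_group" %in% features) {
    band <- 10 * (floor(age / 10))
    out[[length(out) + 1]] <- categorical("age_group",
      sprintf("%d-%d", band, band + 9))
  }
  if ("race" %in% features) out[[length(out) + 1]] <- categorical("race", race_lab)
  if ("ethnicity" %in% features) out[[length(out) + 1]] <- categorical("ethnicity", eth_lab)
  if ("prior_observation" %in% features) {
    out[[length(out) + 1]] <- continuous("prior_observation_days", prior)
  }
  if ("post_observation" %in% features) {
    out[[length(out) + 1]] <- continuous("post_observation_days", post)
  }
  dplyr::bind_rows(out)
}

#' Incidence rates per target cohort
#'
#' For each target cohort: persons enter time-at-risk at their index date
#' plus `tar_start_offset` days; risk ends at the earlier of the end of their
#' observation window (last recorded event) and, when finite,
#' `index + tar_end_offset` days. A person is at risk when the window
#' contains at least one day. The first outcome-cohort event inside the
#' window makes the person a case and censors their time at that event.
#' Person-time is reported in years of 365.25 days; an empty person-time
#' denominator leaves the rate undefined (`NA`, rendered n/a).
#'
#' @param cdm A `cdm_bundle`.
#' @param target_defns A list of [cohort_definition()]s (or a single one).
#' @param outcome_defn The outcome [cohort_definition()].
#' @param tar_start_offset Days after index at which risk starts (default 0).
#' @param tar_end_offset Days after index at which risk ends (default `Inf`:
#'   anchored at the end of observation).
#' @return A tibble of class `incidence_result`: one row per target with
#'   `persons_at_risk`, `cases`, `person_years`, `cases_per_1000_persons`,
#'   `rate_per_1000_py`.
#' @export
incidence_rates <- function(cdm, target_defns, outcome_defn,
                            tar_start_offset = 0, tar_end_offset = Inf) {
  if (inherits(target_defns, "cohort_definition")) target_defns <- list(target_defns)
  outcome_events <- cohort_events(cdm, outcome_defn)
  win <- observation_window(cdm)

  out <- purrr::map(target_defns, function(defn) {
    members <- build_cohort(cdm, defn)
    if (nrow(members) == 0) {
      return(tibble(
        target_cohort_id = defn$cohort_id, outcome_cohort_id = outcome_defn$cohort_id,
        persons_at_risk = 0L, cases = 0L, person_years = 0,
        cases_per_1000_persons = NA_real_, rate_per_1000_py = NA_real_
      ))
    }
    wi <- match(members$person_id, win$person_id)
    risk_start <- members$index_date + tar_start_offset
    risk_end <- win$obs_end[wi]
    if (is.finite(tar_end_offset)) {
      risk_end <- pmin(risk_end, members$index_date + tar_end_offset)
    }
    at_risk <- !is.na(risk_end) & risk_end >= risk_start

    first_outcome <- purrr::map_dbl(seq_len(nrow(members)), function(k) {
      if (!at_risk[k]) return(NA_real_)
      ev <- outcome_events$event_date[outcome_events$person_id == members$person_id[k]]
      ev <- ev[ev >= risk_start[k] & ev <= risk_end[k]]
      if (length(ev) == 0) NA_real_ else as.numeric(min(ev))
    })
    is_case <- !is.na(first_outcome)
    days <- ifelse(is_case,
      first_outcome - as.numeric(risk_start) + 1,
      as.numeric(risk_end) - as.numeric(risk_start) + 1)
    days[!at_risk] <- 0

    persons_at_risk <- sum(at_risk)
    cases <- sum(is_case)
    person_years <- sum(days) / 365.25
    tibble(
      target_cohort_id = defn$cohort_id,
      outcome_cohort_id = outcome_defn$cohort_id,
      persons_at_risk = as.integer(persons_at_risk),
      cases = as.integer(cases),
      person_years = person_years,
      cases_per_1000_persons = if (persons_at_risk == 0) NA_real_ else
        1000 * cases / persons_at_risk,
      rate_per_1000_py = if (person_years == 0) NA_real_ else
        1000 * cases / person_years
    )
  }) %>% dplyr::bind_rows()
  class(out) <- c("incidence_result", class(out))
  out
}

#' Event-cohort pathway sequences
#'
#' For each person, the chronological order of first entry into each event
#' cohort; cohorts entered on the same day collapse into an unordered
#' simultaneous set (rendered `{A+B}` with ids sorted) rather than being
#' given an arbitrary order. Sequence counts sum to the number of persons
#' entering at least one cohort.
#'
#' @param cdm A `cdm_bundle`.
#' @param defns A list of at least two [cohort_definition()]s.
#' @return Tibble `sequence`, `n_persons`, ordered by decreasing count.
#' @export
pathway_sequences <- function(cdm, defns) {
  if (length(defns) < 2) abort("pathway analysis needs at least two event cohorts")
  entries <- purrr::map(defns, function(d) build_cohort(cdm, d)) %>%
    dplyr::bind_rows()
  if (nrow(entries) == 0) {
    return(tibble(sequence = character(), n_persons = integer()))
  }
  seqs <- entries %>%
    dplyr::group_by(.data$person_id) %>%
    dplyr::arrange(.data$index_date, .by_group = TRUE) %>%
    dplyr::group_map(function(g, key) {
      steps <- g %>%
        dplyr::group_by(.data$index_date) %>%
        dplyr::summarise(step = if (dplyr::n() == 1) .data$cohort_id else
          paste0("{", paste(sort(.data$cohort_id), collapse = "+"), "}"),
          .groups = "drop") %>%
        dplyr::arrange(.data$index_date)
      paste(steps$step, collapse = " -> ")
    }) %>% unlist()
  tibble(sequence = seqs) %>%
    dplyr::count(.data$sequence, name = "n_persons") %>%
    dplyr::arrange(dplyr::desc(.data$n_persons), .data$sequence)
}
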
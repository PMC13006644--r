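# Brute-force incidence oracle: per-person day iteration over raw table rows,
# written independently of the incidence_rates() implementation.
oracle_incidence <- function(cdm, target_defn, outcome_defn,
                             start_offset = 0, end_offset = Inf) {
  event_dates <- function(defn, person) {
    cols <- switch(defn$domain,
      condition_occurrence = c("condition_concept_id", "condition_start_date"),
      measurement = c("measurement_concept_id", "measurement_date"),
      observation = c("observation_concept_id", "observation_date"))
    tbl <- cdm$tables[[defn$domain]]
    dates <- as.Date(character())
    for (r in seq_len(nrow(tbl))) {
      if (tbl$person_id[r] != person) next
      if (!tbl[[cols[1]]][r] %in% defn$concept_ids) next
      if (!is.null(defn$value_min) &&
        (is.na(tbl$value_as_number[r]) || tbl$value_as_number[r] < defn$value_min)) next
      if (is.na(tbl[[cols[2]]][r])) next
      dates <- c(dates, tbl[[cols[2]]][r])
    }
    dates
  }
  all_event_dates <- function(person) {
    out <- as.Date(character())
    for (nm in c("visit_occurrence", "measurement", "observation",
      "condition_occurrence")) {
      tbl <- cdm$tables[[nm]]
      dcol <- grep("(start_date|_date)$", names(tbl), value = TRUE)[1]
      out <- c(out, tbl[[dcol]][tbl$person_id == person])
    }
    out[!is.na(out)]
  }

  persons_at_risk <- 0L; cases <- 0L; total_days <- 0
  for (p in cdm$tables$person$person_id) {
    targets <- event_dates(target_defn, p)
    if (length(targets) == 0) next
    index <- min(targets)
    start <- index + start_offset
    end <- max(all_event_dates(p))
    if (is.finite(end_offset)) end <- min(end, index + end_offset)
    if (end < start) next
    persons_at_risk <- persons_at_risk + 1L
    outcomes <- event_dates(outcome_defn, p)
    day <- start; days <- 0; hit <- FALSE
    while (day <= end) {
      days <- days + 1
      if (any(outcomes == day)) { hit <- TRUE; break }
      day <- day + 1
    }
    if (hit) cases <- cases + 1L
    total_days <- total_days + days
  }
  py <- total_days / 365.25
  list(persons_at_risk = persons_at_risk, cases = cases, person_years = py,
    rate = if (py == 0) NA_real_ else 1000 * cases / py,
    per_1000_persons = if (persons_at_risk == 0) NA_real_ else
      1000 * cases / persons_at_risk)
}
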
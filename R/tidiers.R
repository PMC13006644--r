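#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col labs facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a mapping plan into one row per variable decision
#'
#' @param x A `mapping_plan`.
#' @param ... Unused.
#' @return Tibble `variable_id`, `status` (`mapped` / `review`), `reason`,
#'   `target_concept_id`, `target_domain`.
#' @method tidy mapping_plan
#' @export
tidy.mapping_plan <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$entries, status = "mapped", reason = NA_character_),
    dplyr::mutate(
      dplyr::distinct(x$review_queue, .data$variable_id, .keep_all = TRUE),
      status = "review", target_concept_id = NA_real_,
      target_domain = NA_character_, unit_concept_id = NA_real_
    )
  ) %>%
    dplyr::select("variable_id", "status", "reason", "target_concept_id",
      "target_domain") %>%
    dplyr::arrange(.data$variable_id)
}

#' @rdname tidy.mapping_plan
#' @method glance mapping_plan
#' @export
glance.mapping_plan <- function(x, ...) {
  tibble(
    n_variables = x$n_variables, n_mapped = nrow(x$entries),
    n_review = dplyr::n_distinct(x$review_queue$variable_id),
    coverage = x$coverage
  )
}

#' Tidy / summarise a quality report
#'
#' `tidy()` returns the per-check results (without the violating-keys
#' list-column); `glance()` the one-row overall rollup.
#'
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::select(x$results, -"violating_keys")
}

#' @rdname tidy.qc_report
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tot <- x$rollup[x$rollup$category == "Total" & x$rollup$context == "Total", ]
  tibble(
    n_checks = x$n_checks, pass = tot$pass, fail = tot$fail,
    not_applicable = x$n_checks - tot$total, pct_pass = tot$pct_pass
  )
}

#' Row counts of a CDM bundle
#'
#' @param x A `cdm_bundle`.
#' @param ... Unused.
#' @return One row with per-table counts plus error-log size.
#' @method glance cdm_bundle
#' @export
glance.cdm_bundle <- function(x, ...) {
  counts <- purrr::map_int(x$tables, nrow)
  dplyr::bind_cols(
    as_tibble(as.list(counts)),
    tibble(error_log_entries = nrow(x$error_log))
  )
}

#' Plot the pass rates of a quality report
#'
#' Bar chart of percent-pass by Kahn category, faceted by context.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  roll <- object$rollup
  roll <- roll[roll$category != "Total" & roll$context != "Total" & !is.na(roll$pct_pass), ]
  ggplot(roll, aes(x = .data$category, y = .data$pct_pass)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~context) +
    labs(x = NULL, y = "% checks passing", title = "Data-quality pass rates")
}

#' Plot standard vs local concept composition by domain
#'
#' @param object A `concept_classification` (from [classify_concepts()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concept_classification
#' @export
autoplot.concept_classification <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
    c("n_standard", "n_local"), names_to = "kind", values_to = "n") %>%
    dplyr::mutate(kind = ifelse(.data$kind == "n_standard", "standard", "local"))
  ggplot(long, aes(x = stats::reorder(.data$domain_id, -.data$n), y = .data$n,
    fill = .data$kind)) +
    geom_col() +
    labs(x = NULL, y = "concepts", fill = NULL,
      title = "Standard and local concepts by OMOP domain") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot incidence rates per target cohort
#'
#' @param object An `incidence_result` (from [incidence_rates()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot incidence_result
#' @export
autoplot.incidence_result <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$target_cohort_id,
    y = .data$rate_per_1000_py)) +
    geom_col(fill = "darkorange") +
    labs(x = NULL, y = "incidence per 1,000 person-years",
      title = "Incidence by target cohort")
}
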
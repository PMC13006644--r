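#' Built-in psychometric instrument definitions
#'
#' Returns the packaged definitions of the mental-health screening instruments
#' the toolkit understands. Item codings follow the standard published response
#' ranges: PHQ-9, PHQ-5, GAD-7, EPDS, DASS-21 and CES-D items are scored 0-3,
#' PCL-5 items 0-4, and the PSQ uses its 4-point 1-4 coding. DASS-21 uses the
#' conventional doubling rule (`sum_times_two`) so scores are comparable with
#' the full-length DASS-42, and carries the standard depression / anxiety /
#' stress subscale item assignments. All definitions can be overridden or
#' extended by binding rows to this tibble.
#'
#' `PHQ-9` and `PHQ-5` are both supported as distinct labels: source rosters
#' occasionally use the short form, and the two must not be conflated.
#'
#' @return A tibble with one row per instrument: `instrument_id`, `n_items`,
#'   `item_min`, `item_max`, `score_rule` (`"sum"` or `"sum_times_two"`) and a
#'   `subscales` list-column (named list of item index vectors, or `NULL`).
#' @export
#' @examples
#' instrument_definitions()
instrument_definitions <- function() {
  tibble(
    instrument_id = c("PHQ-9", "PHQ-5", "GAD-7", "EPDS", "DASS-21", "CES-D", "PCL-5", "PSQ"),
    n_items  = c(9L, 5L, 7L, 10L, 21L, 20L, 20L, 30L),
    item_min = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),
    item_max = c(3L, 3L, 3L, 3L, 3L, 3L, 4L, 4L),
    score_rule = c("sum", "sum", "sum", "sum", "sum_times_two", "sum", "sum", "sum"),
    subscales = list(
      NULL, NULL, NULL, NULL,
      list(
        depression = c(3L, 5L, 10L, 13L, 16L, 17L, 21L),
        anxiety    = c(2L, 4L, 7L, 9L, 15L, 19L, 20L),
        stress     = c(1L, 6L, 8L, 11L, 12L, 14L, 18L)
      ),
      NULL, NULL, NULL
    )
  )
}

#' Look up a single instrument definition
#'
#' @param instrument_id Instrument label, e.g. `"PHQ-9"`.
#' @param defns Definition table, by default [instrument_definitions()].
#' @return A one-row tibble (same columns as [instrument_definitions()]).
#' @export
instrument_definition <- function(instrument_id, defns = instrument_definitions()) {
  hit <- defns[defns$instrument_id == instrument_id, ]
  if (nrow(hit) != 1) {
    abort(sprintf("unknown instrument '%s'", instrument_id))
  }
  hit
}

#' Score one administration of an instrument
#'
#' Computes the composite total (and subscale totals where defined) from an
#' ordered vector of item responses. Under the default completeness policy any
#' missing item leaves the total absent and marks the administration
#' incomplete; no prorating is applied unless `prorate = TRUE`.
#'
#' @param defn One-row instrument definition (see [instrument_definition()]).
#' @param items Numeric vector of item responses in item order, length
#'   `n_items`; `NA` marks a missing item.
#' @param on_invalid What to do with an item outside the instrument's response
#'   range: `"error"` (default) aborts naming the offending item index;
#'   `"treat_missing"` treats it as a missing item, so the administration
#'   becomes incomplete while the raw value stays available upstream.
#' @param prorate If `TRUE`, administrations with at least 80% of items answered
#'   are prorated (mean item value times `n_items`, rounded); off by default.
#' @return One-row tibble: `instrument_id`, `total`, `n_items_missing`,
#'   `complete`, and a `subscales` list-column of named subscale totals.
#' @export
#' @examples
#' phq9 <- instrument_definition("PHQ-9")
#' score_instrument(phq9, rep(3, 9))$total  # 27
score_instrument <- function(defn, items,
                             on_invalid = c("error", "treat_missing"),
                             prorate = FALSE) {
  on_invalid <- match.arg(on_invalid)
  if (length(items) != defn$n_items) {
    abort(sprintf(
      "'%s' expects %d items, got %d", defn$instrument_id, defn$n_items, length(items)
    ))
  }
  items <- as.numeric(items)
  bad <- which(!is.na(items) & (items < defn$item_min | items > defn$item_max))
  if (length(bad) > 0) {
    if (on_invalid == "error") {
      abort(sprintf(
        "item %d of '%s' is outside its response range [%d, %d]: %s",
        bad[1], defn$instrument_id, defn$item_min, defn$item_max, items[bad[1]]
      ))
    }
    items[bad] <- NA_real_
  }

  n_missing <- sum(is.na(items))
  complete <- n_missing == 0L
  mult <- if (defn$score_rule == "sum_times_two") 2 else 1

  total <- NA_real_
  if (complete) {
    total <- mult * sum(items)
  } else if (prorate && mean(!is.na(items)) >= 0.8) {
    total <- round(mult * mean(items, na.rm = TRUE) * defn$n_items)
  }

  sub <- defn$subscales[[1]]
  sub_totals <- NULL
  if (!is.null(sub)) {
    sub_totals <- lapply(sub, function(idx) {
      vals <- items[idx]
      if (anyNA(vals)) NA_real_ else mult * sum(vals)
    })
  }

  tibble(
    instrument_id = defn$instrument_id,
    total = total,
    n_items_missing = as.integer(n_missing),
    complete = complete && !anyNA(total),
    subscales = list(sub_totals)
  )
}

# Item position lookup for a bundle: item variables of an instrument ordered by
# variable_id (generator ids are zero-padded so lexicographic order is item order).
instrument_item_order <- function(variables, instrument_id) {
  ids <- variables$variable_id[!is.na(variables$instrument_id) &
    variables$instrument_id == instrument_id]
  sort(ids)
}

#' Score every administered instrument instance in a staging bundle
#'
#' One score per (individual, wave, instrument) triple with at least one item
#' response. Items without a response row are treated as missing.
#'
#' @param bundle A `staging_bundle`.
#' @param defns Instrument definition table, default [instrument_definitions()].
#' @inheritParams score_instrument
#' @return Tibble: `individual_id`, `wave_id`, `instrument_id`, `total`,
#'   `n_items_missing`, `complete`, `subscales` (list-column).
#' @export
wave_scores <- function(bundle, defns = instrument_definitions(),
                        on_invalid = c("error", "treat_missing"),
                        prorate = FALSE) {
  on_invalid <- match.arg(on_invalid)
  vars <- bundle$variables
  item_vars <- vars[!is.na(vars$instrument_id), c("variable_id", "instrument_id")]
  resp <- dplyr::inner_join(bundle$responses, item_vars, by = "variable_id")
  if (nrow(resp) == 0) {
    return(tibble(
      individual_id = character(), wave_id = character(),
      instrument_id = character(), total = numeric(),
      n_items_missing = integer(), complete = logical(), subscales = list()
    ))
  }

  instruments <- unique(resp$instrument_id)
  out <- purrr::map(instruments, function(ins) {
    defn <- instrument_definition(ins, defns)
    order_ids <- instrument_item_order(vars, ins)
    if (length(order_ids) != defn$n_items) {
      abort(sprintf(
        "bundle defines %d item variables for '%s' but the instrument has %d items",
        length(order_ids), ins, defn$n_items
      ))
    }
    sub <- resp[resp$instrument_id == ins, ]
    # vectorised scoring: one row per administered instance, one column per
    # item; semantics identical to score_instrument() on the item vector
    key <- paste(sub$individual_id, sub$wave_id, sep = "\r")
    keys <- unique(key)
    mat <- matrix(NA_real_, nrow = length(keys), ncol = defn$n_items)
    mat[cbind(match(key, keys), match(sub$variable_id, order_ids))] <-
      sub$numeric_value
    bad <- !is.na(mat) & (mat < defn$item_min | mat > defn$item_max)
    if (any(bad)) {
      if (on_invalid == "error") {
        first <- which(bad, arr.ind = TRUE)[1, ]
        abort(sprintf(
          "item %d of '%s' is outside its response range [%d, %d]: %s",
          first[["col"]], defn$instrument_id, defn$item_min, defn$item_max,
          mat[first[["row"]], first[["col"]]]
        ))
      }
      mat[bad] <- NA_real_
    }
    mult <- if (defn$score_rule == "sum_times_two") 2 else 1
    n_missing <- rowSums(is.na(mat))
    complete <- n_missing == 0
    total <- mult * rowSums(mat)
    if (prorate) {
      prorated <- round(mult * rowMeans(mat, na.rm = TRUE) * defn$n_items)
      usable <- !complete & (1 - n_missing / defn$n_items) >= 0.8
      total[usable] <- prorated[usable]
      complete <- complete | usable
    }
    sub_defs <- defn$subscales[[1]]
    sub_totals <- if (is.null(sub_defs)) {
      rep(list(NULL), length(keys))
    } else {
      per_sub <- lapply(sub_defs, function(idx) mult * rowSums(mat[, idx, drop = FALSE]))
      lapply(seq_along(keys), function(r) lapply(per_sub, function(v) v[r]))
    }
    parts <- matrix(unlist(strsplit(keys, "\r", fixed = TRUE)), ncol = 2, byrow = TRUE)
    tibble(
      individual_id = parts[, 1], wave_id = parts[, 2],
      instrument_id = defn$instrument_id,
      total = ifelse(is.na(total), NA_real_, total),
      n_items_missing = as.integer(n_missing),
      complete = complete & !is.na(total),
      subscales = sub_totals
    )
  })
  dplyr::bind_rows(out) %>%
    dplyr::arrange(.data$individual_id, .data$wave_id, .data$instrument_id)
}
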
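#' OMOP vocabulary registry with a local-concept extension
#'
#' A `concept_registry` models the OMOP vocabulary tables (CONCEPT, VOCABULARY,
#' CONCEPT_RELATIONSHIP) together with a project-local vocabulary used to mint
#' concepts for source terms that have no standard equivalent. Local concepts
#' are assigned identifiers above 2,000,000,000 so they can never collide with
#' standard OMOP concept ids, and — deliberately deviating from the THEMIS
#' convention of confining custom concepts to `*_source_concept_id` fields —
#' are flagged standard (`S`) so they remain usable directly in `*_concept_id`
#' fields and hence in downstream cohort tooling.
#'
#' @param local_vocabulary_id Identifier of the local vocabulary (default
#'   `"LOCAL"`).
#' @param local_vocabulary_name Display name for the local vocabulary entry.
#' @return An object of class `concept_registry` with tibbles `concepts`,
#'   `vocabularies`, `relationships`.
#' @export
concept_registry <- function(local_vocabulary_id = "LOCAL",
                             local_vocabulary_name = "Local Custom Vocabulary") {
  structure(
    list(
      concepts = empty_concept_table(),
      vocabularies = tibble(
        vocabulary_id = local_vocabulary_id,
        vocabulary_name = local_vocabulary_name,
        vocabulary_reference = "local",
        vocabulary_version = "v1",
        vocabulary_concept_id = 0
      ),
      relationships = empty_relationship_table(),
      local_vocabulary_id = local_vocabulary_id
    ),
    class = "concept_registry"
  )
}

LOCAL_ID_FLOOR <- 2e9

omop_domains <- function() {
  c(
    "Observation", "Meas Value", "Measurement", "Condition", "Geography",
    "Metadata", "Race", "Gender", "Condition Status", "Ethnicity",
    "Type Concept", "Visit"
  )
}

empty_concept_table <- function() {
  tibble(
    concept_id = numeric(), concept_name = character(), domain_id = character(),
    vocabulary_id = character(), concept_class_id = character(),
    standard_concept = character(), concept_code = character(),
    valid_start_date = as.Date(character()), valid_end_date = as.Date(character()),
    invalid_reason = character()
  )
}

empty_relationship_table <- function() {
  tibble(
    concept_id_1 = numeric(), concept_id_2 = numeric(),
    relationship_id = character(),
    valid_start_date = as.Date(character()), valid_end_date = as.Date(character())
  )
}

#' @export
print.concept_registry <- function(x, ...) {
  n_local <- sum(x$concepts$vocabulary_id == x$local_vocabulary_id)
  cat(
    "<concept_registry>", nrow(x$concepts), "concepts (",
    n_local, "local, vocabulary", paste0("'", x$local_vocabulary_id, "'"), "),",
    nrow(x$relationships), "relationship rows\n"
  )
  invisible(x)
}

default_valid_dates <- function(n) {
  list(
    start = rep(as.Date("1970-01-01"), n),
    end = rep(as.Date("2099-12-31"), n)
  )
}

#' Register externally defined (standard) concepts
#'
#' Adds rows to the registry's concept table, typically standard OMOP concepts
#' the study relies on (gender, race, ethnicity, type, visit and condition
#' concepts). Duplicate concept ids are rejected.
#'
#' @param registry A `concept_registry`.
#' @param concepts Tibble with at least `concept_id`, `concept_name`,
#'   `domain_id`, `vocabulary_id`; remaining CONCEPT columns are defaulted.
#' @return The updated registry.
#' @export
register_concepts <- function(registry, concepts) {
  assert_columns(concepts, c("concept_id", "concept_name", "domain_id", "vocabulary_id"),
    "concepts")
  bad_dom <- setdiff(unique(concepts$domain_id), omop_domains())
  if (length(bad_dom) > 0) {
    abort(sprintf("unknown domain_id: %s", paste(bad_dom, collapse = ", ")))
  }
  dates <- default_valid_dates(nrow(concepts))
  rows <- tibble(
    concept_id = as.numeric(concepts$concept_id),
    concept_name = concepts$concept_name,
    domain_id = concepts$domain_id,
    vocabulary_id = concepts$vocabulary_id,
    concept_class_id = concepts[["concept_class_id"]] %||% rep("Clinical Finding", nrow(concepts)),
    standard_concept = concepts[["standard_concept"]] %||% rep("S", nrow(concepts)),
    concept_code = concepts[["concept_code"]] %||% as.character(concepts$concept_id),
    valid_start_date = concepts[["valid_start_date"]] %||% dates$start,
    valid_end_date = concepts[["valid_end_date"]] %||% dates$end,
    invalid_reason = concepts[["invalid_reason"]] %||% rep(NA_character_, nrow(concepts))
  )
  clash <- intersect(rows$concept_id, registry$concepts$concept_id)
  if (length(clash) > 0) {
    abort(sprintf("concept_id already registered: %s",
      paste(format(clash, scientific = FALSE), collapse = ", ")))
  }
  vocabs <- setdiff(unique(rows$vocabulary_id), registry$vocabularies$vocabulary_id)
  if (length(vocabs) > 0) {
    registry$vocabularies <- dplyr::bind_rows(
      registry$vocabularies,
      tibble(
        vocabulary_id = vocabs, vocabulary_name = vocabs,
        vocabulary_reference = "external", vocabulary_version = "n/a",
        vocabulary_concept_id = 0
      )
    )
  }
  registry$concepts <- dplyr::bind_rows(registry$concepts, rows)
  registry
}

local_concepts <- function(registry) {
  registry$concepts[registry$concepts$vocabulary_id == registry$local_vocabulary_id, ]
}

#' Mint a local concept in the 2-billion identifier range
#'
#' Allocates the next sequential local concept id — `max(2e9, highest existing
#' local id) + 1`, so the first minted concept is 2,000,000,001 — and adds the
#' concept under the registry's local vocabulary, standard-flagged `S`.
#' Minting is idempotent on (name, domain): re-minting an existing pair warns
#' and returns the registry unchanged, with the existing concept reported by
#' [minted_concepts()].
#'
#' @param registry A `concept_registry`.
#' @param name Concept name.
#' @param domain_id OMOP domain for the new concept.
#' @param concept_class_id Concept class label (default `"Survey"`).
#' @return The updated registry; the minted (or pre-existing) concept row is
#'   available via [minted_concepts()].
#' @export
#' @examples
#' reg <- mint_local_concept(concept_registry(), "worry frequency", "Observation")
#' minted_concepts(reg)$concept_id  # 2000000001
mint_local_concept <- function(registry, name, domain_id,
                               concept_class_id = "Survey") {
  mint_local_concepts(
    registry,
    tibble(name = name, domain_id = domain_id, concept_class_id = concept_class_id)
  )
}

#' Mint several local concepts at once
#'
#' Vectorised version of [mint_local_concept()]; ids are allocated sequentially
#' in row order.
#'
#' @param registry A `concept_registry`.
#' @param spec Tibble with columns `name`, `domain_id` and optionally
#'   `concept_class_id`.
#' @return The updated registry (minted rows via [minted_concepts()]).
#' @export
mint_local_concepts <- function(registry, spec) {
  assert_columns(spec, c("name", "domain_id"), "mint spec")
  bad <- setdiff(unique(spec$domain_id), omop_domains())
  if (length(bad) > 0) abort(sprintf("unknown domain_id: %s", paste(bad, collapse = ", ")))

  minted <- empty_concept_table()
  for (i in seq_len(nrow(spec))) {
    loc <- local_concepts(registry)
    existing <- loc[loc$concept_name == spec$name[i] & loc$domain_id == spec$domain_id[i], ]
    if (nrow(existing) > 0) {
      warn(sprintf(
        "local concept ('%s', %s) already minted as %s; returning existing concept",
        spec$name[i], spec$domain_id[i],
        format(existing$concept_id[1], scientific = FALSE)
      ))
      minted <- dplyr::bind_rows(minted, existing[1, ])
      next
    }
    new_id <- max(LOCAL_ID_FLOOR, loc$concept_id) + 1
    dates <- default_valid_dates(1)
    row <- tibble(
      concept_id = new_id,
      concept_name = spec$name[i],
      domain_id = spec$domain_id[i],
      vocabulary_id = registry$local_vocabulary_id,
      concept_class_id = (spec[["concept_class_id"]] %||% rep("Survey", nrow(spec)))[i],
      standard_concept = "S",
      concept_code = sprintf("LOC-%d", as.integer(new_id - LOCAL_ID_FLOOR)),
      valid_start_date = dates$start, valid_end_date = dates$end,
      invalid_reason = NA_character_
    )
    registry$concepts <- dplyr::bind_rows(registry$concepts, row)
    minted <- dplyr::bind_rows(minted, row)
  }
  attr(registry, "minted") <- minted
  registry
}

#' Concepts minted by the most recent minting call
#'
#' @param registry A `concept_registry` returned by [mint_local_concept()] or
#'   [mint_local_concepts()].
#' @return Tibble of concept rows (CONCEPT columns).
#' @export
minted_concepts <- function(registry) {
  attr(registry, "minted") %||% empty_concept_table()
}

relationship_inverses <- function() {
  c(
    "Maps to" = "Maps from", "Maps from" = "Maps to",
    "Has answer" = "Is an answer of", "Is an answer of" = "Has answer"
  )
}

#' Add a concept relationship together with its inverse
#'
#' Every semantic link is stored as a pair: the forward row and its inverse
#' (`Maps to` / `Maps from`, `Has answer` / `Is an answer of`), each exactly
#' once; repeated calls are idempotent.
#'
#' @param registry A `concept_registry`.
#' @param concept_id_1,concept_id_2 Concept ids already present in the registry.
#' @param relationship_id One of `"Maps to"`, `"Maps from"`, `"Has answer"`,
#'   `"Is an answer of"`.
#' @return The updated registry.
#' @export
pair_relationship <- function(registry, concept_id_1, concept_id_2, relationship_id) {
  inv <- relationship_inverses()
  if (!relationship_id %in% names(inv)) {
    abort(sprintf("unknown relationship_id '%s'", relationship_id))
  }
  ids <- c(concept_id_1, concept_id_2)
  missing <- ids[!ids %in% registry$concepts$concept_id]
  if (length(missing) > 0) {
    abort(sprintf("concept id(s) not in registry: %s",
      paste(format(missing, scientific = FALSE), collapse = ", ")))
  }
  dates <- default_valid_dates(2)
  fwd <- c(concept_id_1, concept_id_2)
  rev <- c(concept_id_2, concept_id_1)
  rels <- c(relationship_id, unname(inv[relationship_id]))
  rows <- tibble(
    concept_id_1 = fwd, concept_id_2 = rev, relationship_id = rels,
    valid_start_date = dates$start, valid_end_date = dates$end
  )
  combined <- dplyr::bind_rows(registry$relationships, rows)
  registry$relationships <- dplyr::distinct(
    combined, .data$concept_id_1, .data$concept_id_2, .data$relationship_id,
    .keep_all = TRUE
  )
  registry
}

#' Classify registry concepts as standard vs local, per domain
#'
#' Partitions the registry by membership in the local vocabulary and counts
#' concepts per OMOP domain. Counts are conserved: the per-domain totals sum
#' to the registry size.
#'
#' @param registry A non-empty `concept_registry`.
#' @return A tibble of class `concept_classification`: `domain_id`,
#'   `n_standard`, `n_local`, `n_total`, ordered by decreasing total.
#' @export
classify_concepts <- function(registry) {
  if (nrow(registry$concepts) == 0) abort("registry has no concepts to classify")
  out <- registry$concepts %>%
    dplyr::mutate(local = .data$vocabulary_id == registry$local_vocabulary_id) %>%
    dplyr::group_by(.data$domain_id) %>%
    dplyr::summarise(
      n_standard = sum(!.data$local), n_local = sum(.data$local),
      n_total = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$n_total), .data$domain_id)
  class(out) <- c("concept_classification", class(out))
  out
}

#' Build the packaged composition fixture vocabulary
#'
#' A synthetic 255-concept registry whose standard/local composition per OMOP
#' domain mirrors the harmonised vocabulary accounting this toolkit is built
#' around: 227 standard concepts (Observation 108, Meas Value 69, Measurement
#' 9, Condition 25, Gender 2, Race 5, Geography 3, Metadata 2, and one each in
#' Ethnicity, Condition Status, Type Concept and Visit) plus 28 local concepts
#' (Observation 20, Meas Value 6, Measurement 2), all local concepts
#' standard-flagged. Concept names and ids are generated; only the composition
#' is meaningful.
#'
#' @param local_vocabulary_id Local vocabulary label (default `"LOCAL"`).
#' @return A `concept_registry` with exactly 255 concepts.
#' @export
build_fixture_vocabulary <- function(local_vocabulary_id = "LOCAL") {
  standard_counts <- c(
    "Observation" = 108, "Meas Value" = 69, "Measurement" = 9, "Condition" = 25,
    "Ethnicity" = 1, "Condition Status" = 1, "Type Concept" = 1, "Visit" = 1,
    "Gender" = 2, "Race" = 5, "Geography" = 3, "Metadata" = 2
  )
  local_counts <- c("Observation" = 20, "Meas Value" = 6, "Measurement" = 2)

  reg <- concept_registry(local_vocabulary_id = local_vocabulary_id)

  std_domains <- rep(names(standard_counts), standard_counts)
  n_std <- length(std_domains)
  std <- tibble(
    concept_id = 40000000 + seq_len(n_std),
    concept_name = sprintf("Standard %s concept %03d", std_domains,
      stats::ave(seq_len(n_std), std_domains, FUN = seq_along)),
    domain_id = std_domains,
    vocabulary_id = ifelse(std_domains %in% c("Measurement", "Meas Value"),
      "LOINC", "SNOMED")
  )
  reg <- register_concepts(reg, std)

  loc_domains <- rep(names(local_counts), local_counts)
  reg <- mint_local_concepts(reg, tibble(
    name = sprintf("Local %s concept %02d", loc_domains,
      stats::ave(seq_along(loc_domains), loc_domains, FUN = seq_along)),
    domain_id = loc_domains
  ))

  # Each local concept maps to itself being the standard; link a sample of
  # local concepts to standard counterparts to exercise the pairing invariant.
  loc <- local_concepts(reg)
  std_obs <- reg$concepts$concept_id[reg$concepts$domain_id == "Observation" &
    reg$concepts$vocabulary_id != local_vocabulary_id]
  for (i in seq_len(min(5, nrow(loc)))) {
    reg <- pair_relationship(reg, loc$concept_id[i], std_obs[i], "Maps to")
  }
  reg
}

athena_files <- function() {
  c(
    concepts = "CONCEPT.csv", vocabularies = "VOCABULARY.csv",
    relationships = "CONCEPT_RELATIONSHIP.csv"
  )
}

#' Write a registry as Athena-style vocabulary files
#'
#' Tab-separated, header row, no quoting, dates as `YYYYMMDD` — the de-facto
#' vocabulary-download dialect consumed across the OMOP ecosystem.
#'
#' @param registry A `concept_registry`.
#' @param path Target directory.
#' @return Invisibly, a manifest tibble (`file`, `path`, `n_rows`, `md5`).
#' @export
write_vocabulary <- function(registry, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))

  fmt_dates <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(~ inherits(.x, "Date")),
      ~ format(.x, "%Y%m%d")))
  }
  tables <- list(
    concepts = fmt_dates(registry$concepts),
    vocabularies = registry$vocabularies,
    relationships = fmt_dates(registry$relationships)
  )
  files <- athena_files()
  manifest <- purrr::imap(tables, function(tbl, nm) {
    f <- file.path(path, files[[nm]])
    readr::write_tsv(tbl, f, na = "", quote = "none", escape = "none",
      progress = FALSE)
    tibble(file = files[[nm]], path = f, n_rows = nrow(tbl),
      md5 = unname(tools::md5sum(f)))
  })
  invisible(dplyr::bind_rows(manifest))
}

#' Load a registry from Athena-style vocabulary files
#'
#' @param path Directory holding `CONCEPT.csv`, `VOCABULARY.csv`,
#'   `CONCEPT_RELATIONSHIP.csv` in the tab-separated Athena dialect.
#' @param local_vocabulary_id Which vocabulary id is the local extension
#'   (default `"LOCAL"`).
#' @return A `concept_registry`.
#' @export
load_vocabulary <- function(path, local_vocabulary_id = "LOCAL") {
  files <- athena_files()
  read_one <- function(nm, col_types) {
    f <- file.path(path, files[[nm]])
    if (!file.exists(f)) abort(sprintf("missing vocabulary file: %s", f))
    readr::read_tsv(f, col_types = col_types, na = "", progress = FALSE,
      quote = "")
  }
  parse_ymd <- function(x) as.Date(as.character(x), format = "%Y%m%d")

  concepts <- read_one("concepts", readr::cols(
    concept_id = "d", concept_name = "c", domain_id = "c", vocabulary_id = "c",
    concept_class_id = "c", standard_concept = "c", concept_code = "c",
    valid_start_date = "c", valid_end_date = "c", invalid_reason = "c"
  )) %>%
    dplyr::mutate(
      valid_start_date = parse_ymd(.data$valid_start_date),
      valid_end_date = parse_ymd(.data$valid_end_date)
    )
  dups <- concepts$concept_id[duplicated(concepts$concept_id)]
  if (length(dups) > 0) {
    abort(sprintf("duplicate concept_id in CONCEPT file: %s",
      paste(format(unique(dups), scientific = FALSE), collapse = ", ")))
  }
  vocabularies <- read_one("vocabularies", readr::cols(
    vocabulary_id = "c", vocabulary_name = "c", vocabulary_reference = "c",
    vocabulary_version = "c", vocabulary_concept_id = "d"
  ))
  relationships <- read_one("relationships", readr::cols(
    concept_id_1 = "d", concept_id_2 = "d", relationship_id = "c",
    valid_start_date = "c", valid_end_date = "c"
  )) %>%
    dplyr::mutate(
      valid_start_date = parse_ymd(.data$valid_start_date),
      valid_end_date = parse_ymd(.data$valid_end_date)
    )

  reg <- concept_registry(local_vocabulary_id = local_vocabulary_id)
  reg$concepts <- concepts
  reg$vocabularies <- vocabularies
  reg$relationships <- relationships
  reg
}
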
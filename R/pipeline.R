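#' Load a pipeline configuration
#'
#' One top-level YAML (or JSON) file with per-phase sections: `study` (the
#' [study_config()] fields), optional `inject` (the [error_spec()] counts),
#' `etl` (the [etl_config()] fields), and optional `cohorts` /
#' `incidence` sections. Fields not given fall back to the packaged
#' defaults. The manifest timestamp comes from the config (`timestamp`
#' field), never from the wall clock, so reruns are byte-identical.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A named list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  structure(raw, class = "pipeline_config")
}

config_study <- function(cfg) do.call(study_config, cfg$study %||% list())

config_etl <- function(cfg) {
  args <- cfg$etl %||% list()
  if (!is.null(args$condition_rules)) {
    args$condition_rules <- dplyr::bind_rows(args$condition_rules)
  }
  do.call(etl_config, args)
}

manifest_path <- function(workdir) file.path(workdir, "run_manifest.json")

read_manifest <- function(workdir) {
  p <- manifest_path(workdir)
  if (file.exists(p)) jsonlite::read_json(p) else
    list(tool_version = as.character(utils::packageVersion("omopsurvey")),
      phases = list())
}

update_manifest <- function(workdir, phase, files, counts, cfg) {
  man <- read_manifest(workdir)
  man$tool_version <- as.character(utils::packageVersion("omopsurvey"))
  man$timestamp <- cfg$timestamp %||% "1970-01-01T00:00:00Z"
  man$seeds <- list(study = (cfg$study %||% list())$seed %||% 1,
    inject = (cfg$inject %||% list())$seed %||% 1)
  digests <- as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  man$phases[[phase]] <- list(output_digests = digests, row_counts = counts)
  jsonlite::write_json(man, manifest_path(workdir), auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

require_artifact <- function(workdir, file, needed_phase, for_phase) {
  if (!file.exists(file.path(workdir, file))) {
    abort(sprintf(
      "phase '%s' needs the output of phase '%s'; run '%s' first (missing %s)",
      for_phase, needed_phase, needed_phase, file
    ))
  }
}

#' Run pipeline phases
#'
#' Programmatic equivalents of the command-line phases. Each phase reads its
#' prerequisites from `workdir`, writes its artifact there, and updates the
#' run manifest (tool version, seeds, per-phase row counts, output file
#' digests). All randomness is seeded from the config; the wall clock is
#' never read, so two runs with the same config produce identical digests.
#'
#' @param cfg A `pipeline_config` (see [load_pipeline_config()]) or a plain
#'   named list with the same shape.
#' @param workdir Working directory for pipeline artifacts.
#' @return The phase's primary artifact, invisibly.
#' @export
phase_synth <- function(cfg, workdir) {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  sc <- config_study(cfg)
  bundle <- generate_study(sc)
  ledger <- empty_ledger()
  if (!is.null(cfg$inject)) {
    spec <- do.call(error_spec, cfg$inject)
    injected <- inject_errors(bundle, spec, reference_date = sc$reference_date)
    bundle <- injected$bundle
    ledger <- injected$ledger
  }
  man <- write_staging(bundle, file.path(workdir, "staging"))
  readr::write_csv(ledger, file.path(workdir, "staging", "injection_ledger.csv"),
    na = "", progress = FALSE)
  update_manifest(workdir, "synth",
    c(man$path, file.path(workdir, "staging", "injection_ledger.csv")),
    as.list(setNames(man$n_rows, man$file)), cfg)
  invisible(bundle)
}

#' @rdname phase_synth
#' @export
phase_vocab_build <- function(cfg, workdir) {
  require_artifact(workdir, "staging/responses.csv", "synth", "vocab-build")
  bundle <- load_staging(file.path(workdir, "staging"))
  built <- build_study_vocabulary(bundle)
  man <- write_vocabulary(built$registry, file.path(workdir, "vocabulary"))
  write_mapping_table(built$mapping, file.path(workdir, "mapping_table.csv"))
  update_manifest(workdir, "vocab-build",
    c(man$path, file.path(workdir, "mapping_table.csv")),
    as.list(setNames(man$n_rows, man$file)), cfg)
  invisible(built$registry)
}

#' @rdname phase_synth
#' @export
phase_map <- function(cfg, workdir) {
  require_artifact(workdir, "vocabulary/CONCEPT.csv", "vocab-build", "map")
  bundle <- load_staging(file.path(workdir, "staging"))
  registry <- load_vocabulary(file.path(workdir, "vocabulary"))
  mapping_table <- read_mapping_table(file.path(workdir, "mapping_table.csv"))
  plan <- compile_mapping_plan(bundle, registry, mapping_table)
  readr::write_csv(plan$entries, file.path(workdir, "mapping_entries.csv"),
    na = "", progress = FALSE)
  readr::write_csv(plan$review_queue, file.path(workdir, "mapping_review_queue.csv"),
    na = "", progress = FALSE)
  update_manifest(workdir, "map",
    file.path(workdir, c("mapping_entries.csv", "mapping_review_queue.csv")),
    list(entries = nrow(plan$entries), review = nrow(plan$review_queue),
      coverage = plan$coverage), cfg)
  invisible(plan)
}

#' @rdname phase_synth
#' @export
phase_etl_run <- function(cfg, workdir) {
  require_artifact(workdir, "mapping_entries.csv", "map", "etl-run")
  bundle <- load_staging(file.path(workdir, "staging"))
  registry <- load_vocabulary(file.path(workdir, "vocabulary"))
  mapping_table <- read_mapping_table(file.path(workdir, "mapping_table.csv"))
  plan <- compile_mapping_plan(bundle, registry, mapping_table)
  cdm <- run_etl(bundle, plan, registry, config_etl(cfg))
  man <- write_cdm(cdm, file.path(workdir, "cdm"))
  update_manifest(workdir, "etl-run", man$path,
    as.list(setNames(man$n_rows, man$file)), cfg)
  invisible(cdm)
}

#' @rdname phase_synth
#' @export
phase_qc_run <- function(cfg, workdir) {
  require_artifact(workdir, "cdm/person.csv", "etl-run", "qc-run")
  cdm <- read_cdm(file.path(workdir, "cdm"))
  registry <- load_vocabulary(file.path(workdir, "vocabulary"))
  bundle <- load_staging(file.path(workdir, "staging"))
  mapping_table <- read_mapping_table(file.path(workdir, "mapping_table.csv"))
  plan <- compile_mapping_plan(bundle, registry, mapping_table)
  suite <- default_check_suite(registry, plan, bundle$variables,
    config = config_etl(cfg))
  report <- run_checks(cdm, registry, suite)
  readr::write_csv(tidy(report), file.path(workdir, "qc_results.csv"),
    na = "", progress = FALSE)
  readr::write_csv(report$rollup, file.path(workdir, "qc_summary.csv"),
    na = "", progress = FALSE)
  update_manifest(workdir, "qc-run",
    file.path(workdir, c("qc_results.csv", "qc_summary.csv")),
    list(checks = report$n_checks), cfg)
  invisible(report)
}

default_cohort_definitions <- function(cfg) {
  rules <- config_etl(cfg)$condition_rules
  defs <- purrr::map(seq_len(nrow(rules)), function(i) {
    cohort_definition(
      cohort_id = paste0("screen_positive_", instrument_slug(rules$instrument_id[i])),
      domain = "condition_occurrence",
      concept_ids = rules$condition_concept_id[i]
    )
  })
  defs
}

#' @rdname phase_synth
#' @export
phase_cohort <- function(cfg, workdir) {
  require_artifact(workdir, "cdm/person.csv", "etl-run", "cohort")
  cdm <- read_cdm(file.path(workdir, "cdm"))
  defns <- default_cohort_definitions(cfg)
  memberships <- dplyr::bind_rows(purrr::map(defns, ~ build_cohort(cdm, .x)))
  readr::write_csv(memberships, file.path(workdir, "cohorts.csv"), na = "",
    progress = FALSE)
  inc <- incidence_rates(cdm, defns[1], defns[[length(defns)]])
  readr::write_csv(inc, file.path(workdir, "incidence.csv"), na = "",
    progress = FALSE)
  paths <- if (length(defns) >= 2) pathway_sequences(cdm, defns) else
    tibble(sequence = character(), n_persons = integer())
  readr::write_csv(paths, file.path(workdir, "pathways.csv"), na = "",
    progress = FALSE)
  update_manifest(workdir, "cohort",
    file.path(workdir, c("cohorts.csv", "incidence.csv", "pathways.csv")),
    list(memberships = nrow(memberships)), cfg)
  invisible(memberships)
}

#' @rdname phase_synth
#' @export
phase_report <- function(cfg, workdir) {
  require_artifact(workdir, "qc_summary.csv", "qc-run", "report")
  man <- read_manifest(workdir)
  invisible(man)
}

#' Run the whole pipeline end to end
#'
#' Chains synth, vocab-build, map, etl-run, qc-run, cohort and report.
#'
#' @inheritParams phase_synth
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(cfg, workdir) {
  phase_synth(cfg, workdir)
  phase_vocab_build(cfg, workdir)
  phase_map(cfg, workdir)
  phase_etl_run(cfg, workdir)
  phase_qc_run(cfg, workdir)
  phase_cohort(cfg, workdir)
  phase_report(cfg, workdir)
  invisible(read_manifest(workdir))
}

#' Command-line entry point
#'
#' Dispatches `omopsurvey <command> --config <file> --workdir <dir>` where
#' command is one of `synth`, `vocab-build`, `map`, `etl-run`, `qc-run`,
#' `cohort`, `report`, or `all`. Each command checks that its prerequisite
#' phase artifacts exist and aborts naming the missing phase otherwise. Used
#' by the installed `inst/cli/omopsurvey` script; exposed as a function so
#' the dispatch logic is testable.
#'
#' @param args Character vector of command-line arguments.
#' @return 0 on success (invisibly); errors propagate to the caller.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  commands <- c("synth", "vocab-build", "map", "etl-run", "qc-run", "cohort",
    "report", "all")
  if (length(args) == 0 || !args[1] %in% commands) {
    abort(paste0("usage: omopsurvey <", paste(commands, collapse = "|"),
      "> --config <file> [--workdir <dir>]"))
  }
  command <- args[1]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  config_path <- get_opt("--config")
  if (is.null(config_path)) abort("--config <file> is required")
  workdir <- get_opt("--workdir", "omopsurvey_run")
  cfg <- load_pipeline_config(config_path)

  phases <- list(
    "synth" = phase_synth, "vocab-build" = phase_vocab_build, "map" = phase_map,
    "etl-run" = phase_etl_run, "qc-run" = phase_qc_run, "cohort" = phase_cohort,
    "report" = phase_report
  )
  if (command == "all") {
    run_pipeline(cfg, workdir)
  } else {
    phases[[command]](cfg, workdir)
  }
  message(sprintf("[omopsurvey] %s completed (workdir: %s)", command, workdir))
  invisible(0L)
}
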
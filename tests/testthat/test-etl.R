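small_etl_inputs <- function(n_individuals = 10, seed = 61, mutate_bundle = identity) {
  cfg <- study_config(
    n_individuals = n_individuals, n_households = 5, n_waves = 2,
    instruments = "GAD-7", covariates = character(0), item_missingness = 0,
    seed = seed
  )
  bundle <- mutate_bundle(generate_study(cfg))
  built <- build_study_vocabulary(bundle)
  plan <- compile_mapping_plan(bundle, built$registry, built$mapping)
  list(bundle = bundle, registry = built$registry, plan = plan, config = cfg)
}

test_that("a clean single-instrument study yields the expected table counts", {
  x <- small_etl_inputs()
  cdm <- run_etl(x$bundle, x$plan, x$registry, etl_config())
  expect_equal(nrow(cdm$tables$person), 10)
  expect_equal(nrow(cdm$tables$visit_occurrence), 20)
  # composite scores to Measurement, the 7 items per administration to Observation
  expect_equal(nrow(cdm$tables$measurement), 20)
  expect_equal(nrow(cdm$tables$observation), 140)
  expect_equal(nrow(cdm$error_log), 0)
  # referential closure by exhaustive join
  for (tbl in c("measurement", "observation", "condition_occurrence")) {
    t <- cdm$tables[[tbl]]
    expect_true(all(t$person_id %in% cdm$tables$person$person_id), info = tbl)
    expect_true(all(t$visit_occurrence_id %in%
      cdm$tables$visit_occurrence$visit_occurrence_id), info = tbl)
  }
})

test_that("a null individual identifier leads to exclusion, not a placeholder", {
  x <- small_etl_inputs(mutate_bundle = function(b) {
    b$individuals$individual_id[4] <- NA_character_
    b
  })
  cdm <- run_etl(x$bundle, x$plan, x$registry, etl_config())
  expect_equal(nrow(cdm$tables$person), 9)
  null_entries <- cdm$error_log[cdm$error_log$rule == "null_person_id", ]
  expect_equal(nrow(null_entries), 1)
  expect_equal(null_entries$action, "excluded")
  # no invented identifiers: every person traces to a real source id
  expect_true(all(!is.na(cdm$tables$person$person_source_value)))
})

test_that("an empty bundle produces empty tables but a complete audit", {
  b <- staging_bundle("empty")
  built <- build_study_vocabulary(b)
  plan <- compile_mapping_plan(b, built$registry, built$mapping)
  cdm <- run_etl(b, plan, built$registry, etl_config())
  for (nm in names(cdm$tables)) expect_equal(nrow(cdm$tables[[nm]]), 0)
  expect_gt(nrow(cdm$execution_summary), 0)
  expect_true(all(cdm$execution_summary$rows_in == 0))
})

test_that("clean_dates nulls future births and pre-birth events with one entry each", {
  recs <- tibble::tibble(individual_id = "i1", row_key = "i1",
    birth_date = as.Date("2050-01-01"))
  out <- clean_dates(recs, reference_date = "2024-01-01",
    date_col = "birth_date", key_col = "row_key")
  expect_true(is.na(out$records$birth_date))
  expect_equal(nrow(out$log), 1)
  expect_equal(out$log$rule, "future_birth_date")
  expect_equal(out$log$action, "nulled")

  ev <- tibble::tibble(individual_id = "p1", row_key = "p1::w1",
    event_date = as.Date("1990-05-01"))
  birth <- tibble::tibble(individual_id = "p1", birth_date = as.Date("2000-01-01"))
  out2 <- clean_dates(ev, birth, reference_date = "2024-01-01",
    date_col = "event_date", key_col = "row_key")
  expect_true(is.na(out2$records$event_date))
  expect_equal(out2$log$rule, "event_before_birth")

  ok <- tibble::tibble(individual_id = "p1", row_key = "p1::w2",
    event_date = as.Date("2010-05-01"))
  out3 <- clean_dates(ok, birth, reference_date = "2024-01-01",
    date_col = "event_date", key_col = "row_key")
  expect_identical(out3$records, ok)
  expect_equal(nrow(out3$log), 0)
})

test_that("absent or unknown demographic codes coalesce to concept 0, ledgered", {
  recs <- tibble::tibble(
    individual_id = c("a", "b", "c"),
    sex_code = c(NA, "F", "X"),
    race_code = c("black", "black", "black"),
    ethnicity_code = c("not_hispanic", "not_hispanic", "not_hispanic")
  )
  out <- apply_demographic_defaults(recs, etl_config())
  expect_equal(out$records$gender_concept_id, c(0, 8532, 0))
  expect_equal(out$records$race_concept_id, rep(8516, 3))
  expect_setequal(out$log$rule,
    c("missing_gender_code", "unmapped_gender_code"))
  expect_true(all(out$log$action == "remapped"))

  clean <- apply_demographic_defaults(recs[2, ], etl_config())
  expect_equal(nrow(clean$log), 0)
})

test_that("every ETL step satisfies rows_in = rows_out + rows_excluded, with a matching log", {
  fix <- corrupt_pipeline_fixture()
  s <- fix$cdm$execution_summary
  expect_true(all(s$rows_in == s$rows_out + s$rows_excluded))
  # per step, exclusions in the summary equal excluded-action log entries
  excluded <- fix$cdm$error_log[fix$cdm$error_log$action == "excluded", ]
  for (k in seq_len(nrow(s))) {
    expect_equal(s$rows_excluded[k], sum(excluded$step == s$step[k]),
      info = s$step[k])
  }
})

test_that("a clean synthetic study maps completely with an empty error log", {
  fix <- clean_pipeline_fixture()
  expect_equal(nrow(fix$cdm$error_log), 0)
  expect_equal(fix$plan$coverage, 1)
  expect_equal(nrow(fix$cdm$tables$person), fix$config$n_individuals)
})

test_that("CDM bundles round-trip through their delimited form", {
  fix <- clean_pipeline_fixture()
  dir <- withr::local_tempdir()
  write_cdm(fix$cdm, dir)
  cdm2 <- read_cdm(dir)
  for (nm in names(fix$cdm$tables)) {
    expect_equal(as.data.frame(cdm2$tables[[nm]]),
      as.data.frame(fix$cdm$tables[[nm]]), info = nm)
  }
  expect_equal(as.data.frame(cdm2$error_log), as.data.frame(fix$cdm$error_log))
  expect_equal(as.data.frame(cdm2$execution_summary),
    as.data.frame(fix$cdm$execution_summary))
})

test_that("rerunning the ETL on identical inputs is byte-identical", {
  x <- small_etl_inputs(seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cdm(run_etl(x$bundle, x$plan, x$registry, etl_config()), d1)
  write_cdm(run_etl(x$bundle, x$plan, x$registry, etl_config()), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("an unresolvable plan is fatal before any table is built", {
  x <- small_etl_inputs()
  x$plan$entries$target_concept_id[1] <- 123456789
  expect_error(run_etl(x$bundle, x$plan, x$registry, etl_config()),
    "absent from the registry")
})
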
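test_that("the packaged suite is broad enough and well-formed", {
  fix <- clean_pipeline_fixture()
  suite <- fix$suite
  expect_gte(nrow(suite), 30)
  # every populated CDM table carries at least one completeness check
  for (tbl in c("person", "visit_occurrence", "measurement", "observation",
    "condition_occurrence", "location")) {
    expect_gte(sum(suite$table == tbl & suite$category == "Completeness"), 1)
  }
  # concept-domain agreement checks exist for the three event tables
  domain_checks <- suite[suite$rule == "concept_in_domain", ]
  expect_true(all(c("measurement", "observation", "condition_occurrence") %in%
    domain_checks$table))
  expect_true(all(suite$category %in%
    c("Conformance", "Completeness", "Plausibility")))
  expect_true(all(suite$context %in% c("Verification", "Validation")))
})

test_that("a clean synthetic study passes completeness and plausibility at 100%", {
  fix <- clean_pipeline_fixture()
  roll <- fix$report$rollup
  for (cat in c("Completeness", "Plausibility")) {
    row <- roll[roll$category == cat & roll$context == "Total", ]
    expect_equal(row$fail, 0)
    expect_equal(row$pct_pass, 100)
  }
})

test_that("event-before-birth rows planted in a CDM are counted exactly", {
  fix <- clean_pipeline_fixture()
  cdm <- fix$cdm
  # plant 3 observations before their persons' births, bypassing the ETL
  idx <- 1:3
  birth_years <- cdm$tables$person$year_of_birth[
    match(cdm$tables$observation$person_id[idx], cdm$tables$person$person_id)]
  cdm$tables$observation$observation_date[idx] <-
    as.Date(sprintf("%d-01-01", birth_years - 1))
  report <- run_checks(cdm, fix$registry, fix$suite)
  res <- report$results[report$results$check_id == "after_birth_observation", ]
  expect_equal(res$rows_violating, 3L)
  expect_equal(res$status, "FAIL")
})

test_that("checks over an empty table are NOT_APPLICABLE and leave rates alone", {
  fix <- clean_pipeline_fixture()
  cdm <- fix$cdm
  cdm$tables$measurement <- cdm$tables$measurement[0, ]
  report <- run_checks(cdm, fix$registry, fix$suite)
  meas <- report$results[report$results$table == "measurement", ]
  expect_true(all(meas$status == "NOT_APPLICABLE"))
  # NOT_APPLICABLE rows are excluded from every rollup denominator
  expect_equal(sum(report$rollup$total[report$rollup$category == "Total" &
    report$rollup$context == "Total"]),
    sum(report$results$status != "NOT_APPLICABLE"))
})

test_that("adding a violating row never decreases a violation count", {
  fix <- clean_pipeline_fixture()
  cdm <- fix$cdm
  base <- run_checks(cdm, fix$registry, fix$suite)
  bad <- cdm$tables$observation[1, ]
  bad$observation_id <- max(cdm$tables$observation$observation_id) + 1L
  bad$person_id <- 999999L  # dangling
  cdm$tables$observation <- dplyr::bind_rows(cdm$tables$observation, bad)
  more <- run_checks(cdm, fix$registry, fix$suite)
  joined <- merge(base$results[, c("check_id", "rows_violating")],
    more$results[, c("check_id", "rows_violating")], by = "check_id")
  expect_true(all(joined$rows_violating.y >= joined$rows_violating.x))
})

test_that("the rollup reproduces the classic pass/fail arithmetic", {
  # 27 failures among 1,861 verification checks round to a 99% pass rate
  results <- tibble::tibble(
    check_id = sprintf("c%04d", 1:1861),
    category = rep(c("Plausibility", "Conformance", "Completeness"),
      times = c(520, 889, 452)),
    context = "Verification",
    rows_evaluated = 1L, rows_violating = 0L, violation_fraction = 0,
    threshold = 0,
    status = "PASS"
  )
  fail_ids <- c(1:4, 521:543)  # 4 plausibility + 23 conformance failures
  results$status[fail_ids] <- "FAIL"
  report <- structure(list(results = results, n_checks = nrow(results)),
    class = "qc_report")
  roll <- summarize_report(report)
  ver_total <- roll[roll$category == "Total" & roll$context == "Verification", ]
  expect_equal(ver_total$pass, 1834)
  expect_equal(ver_total$fail, 27)
  expect_equal(ver_total$total, 1861)
  expect_equal(ver_total$pct_pass, 99)
  # an empty report renders undefined rates as NA, not NaN or zero
  empty <- structure(list(results = results[0, ], n_checks = 0L),
    class = "qc_report")
  roll0 <- summarize_report(empty)
  expect_true(all(is.na(roll0$pct_pass)))
  expect_true(all(roll0$total == 0))
})

test_that("reports are deterministic and a suite naming a bad table is fatal", {
  fix <- clean_pipeline_fixture()
  r1 <- run_checks(fix$cdm, fix$registry, fix$suite)
  r2 <- run_checks(fix$cdm, fix$registry, fix$suite)
  expect_identical(tidy(r1), tidy(r2))

  bad_suite <- check_definition("oops", "Completeness", "Verification",
    "drug_exposure", "person_id", "not_null")
  expect_error(run_checks(fix$cdm, fix$registry, bad_suite), "unknown table")
})

test_that("every injected corruption is either cleaned by ETL or caught by QC", {
  fix <- corrupt_pipeline_fixture()
  rec <- reconcile_injections(fix$ledger, fix$cdm, fix$report)
  expect_equal(nrow(rec), 5)
  expect_equal(rec$accounted, rec$injected)
  expect_equal(sum(rec$injected), nrow(fix$ledger))
  # out-of-range items survive cleaning and must be caught by the range checks
  oor <- rec[rec$rule == "out_of_range_items", ]
  expect_equal(oor$detected_by_qc, oor$injected)
})
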
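make_vars <- function() {
  tibble::tibble(
    variable_id = c("bmi", "phq9_item_01", "notes", "dx_depression"),
    instrument_id = c(NA, "PHQ-9", NA, NA),
    value_kind = c("quantitative", "categorical", "free_text", "categorical"),
    unit_label = c("kg/m2", NA, NA, NA),
    allowed_values = c(NA, "0|1|2|3", NA, "yes|no"),
    is_diagnosis = c(FALSE, FALSE, FALSE, TRUE)
  )
}

test_that("domain routing is total and follows the unit/flag rules", {
  routed <- route_domain(make_vars())
  expect_equal(routed$target_domain,
    c("Measurement", "Observation", "Observation", "Condition"))
})

test_that("resolvable, absent, and deprecated mappings are triaged correctly", {
  reg <- register_concepts(concept_registry(), tibble::tibble(
    concept_id = c(3038553, 4149320),
    concept_name = c("Body mass index", "Old concept"),
    domain_id = c("Measurement", "Observation"),
    vocabulary_id = "LOINC",
    valid_end_date = as.Date(c("2099-12-31", "2001-01-01"))
  ))
  vars <- make_vars()[c(1, 2, 3), ]
  bundle <- staging_bundle("s",
    waves = tibble::tibble(wave_id = "w1", study_id = "s", wave_index = 1L,
      wave_date = as.Date("2020-06-01")),
    variables = vars)
  mt <- tibble::tibble(
    variable_id = c("bmi", "notes"),
    target_concept_id = c(3038553, 4149320),
    target_domain = c("Measurement", NA),
    value_label = NA_character_, value_concept_id = NA_real_,
    unit_concept_id = NA_real_
  )
  plan <- compile_mapping_plan(bundle, reg, mt)
  expect_equal(plan$entries$variable_id, "bmi")
  rq <- plan$review_queue
  expect_setequal(rq$variable_id, c("phq9_item_01", "notes"))
  expect_equal(rq$reason[rq$variable_id == "phq9_item_01"], "no_equivalent")
  expect_equal(rq$reason[rq$variable_id == "notes"], "deprecated")
  # totality: every distinct variable gets exactly one decision
  expect_equal(nrow(plan$entries) + dplyr::n_distinct(rq$variable_id),
    dplyr::n_distinct(bundle$variables$variable_id))
})

test_that("an unknown target concept routes to review, never drops silently", {
  reg <- concept_registry()
  vars <- make_vars()[1, ]
  bundle <- staging_bundle("s",
    waves = tibble::tibble(wave_id = "w1", study_id = "s", wave_index = 1L,
      wave_date = as.Date("2020-06-01")),
    variables = vars)
  mt <- tibble::tibble(variable_id = "bmi", target_concept_id = 999999,
    target_domain = "Measurement", value_label = NA_character_,
    value_concept_id = NA_real_, unit_concept_id = NA_real_)
  plan <- compile_mapping_plan(bundle, reg, mt)
  expect_equal(nrow(plan$entries), 0)
  expect_equal(plan$review_queue$reason, "no_equivalent")
})

test_that("coverage is the mapped fraction, and 1 for an empty study", {
  fix <- clean_pipeline_fixture()
  expect_equal(fix$plan$coverage, 1)

  # drop one variable's mapping: coverage = (n-1)/n
  mt <- fix$mapping[fix$mapping$variable_id != "employment_status", ]
  plan <- compile_mapping_plan(fix$bundle, fix$registry, mt)
  n <- dplyr::n_distinct(fix$bundle$variables$variable_id)
  expect_equal(plan$coverage, (n - 1) / n)

  empty_plan <- compile_mapping_plan(staging_bundle("empty"), fix$registry,
    fix$mapping)
  expect_equal(empty_plan$coverage, 1)
})

test_that("plan compilation is deterministic and tidiers report it faithfully", {
  fix <- clean_pipeline_fixture()
  p1 <- compile_mapping_plan(fix$bundle, fix$registry, fix$mapping)
  p2 <- compile_mapping_plan(fix$bundle, fix$registry, fix$mapping)
  expect_identical(tidy(p1), tidy(p2))
  g <- glance(p1)
  expect_equal(g$n_mapped + g$n_review, g$n_variables)
  expect_true(all(p1$entries$target_concept_id %in%
    fix$registry$concepts$concept_id))
})

test_that("mapping tables round-trip through their CSV form", {
  fix <- clean_pipeline_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_mapping_table(fix$mapping, path)
  mt2 <- read_mapping_table(path)
  expect_equal(as.data.frame(mt2), as.data.frame(fix$mapping))
})
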
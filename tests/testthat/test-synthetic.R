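test_that("an empty roster produces an empty but well-formed bundle", {
  b <- generate_study(study_config(n_individuals = 0, n_households = 0, seed = 1))
  expect_equal(nrow(b$individuals), 0)
  expect_equal(nrow(b$responses), 0)
  expect_equal(nrow(b$waves), 2)
})

test_that("response counts follow individuals x waves x items with no missingness", {
  b <- generate_study(study_config(
    n_individuals = 10, n_waves = 2, instruments = "GAD-7",
    covariates = character(0), item_missingness = 0, seed = 5
  ))
  expect_equal(nrow(b$responses), 10 * 2 * 7)
  expect_error(
    generate_study(study_config(instruments = "NOT-A-SCALE")),
    "unknown instrument"
  )
})

test_that("realised missingness sits inside the exact binomial 99% band", {
  cfg <- study_config(
    n_individuals = 60, n_waves = 2, instruments = c("PHQ-9", "GAD-7"),
    covariates = character(0), item_missingness = 0.5, seed = 12
  )
  b <- generate_study(cfg)
  n_cells <- 60 * 2 * (9 + 7)
  observed_missing <- n_cells - nrow(b$responses)
  # independent oracle: the exact central binomial interval for n trials
  bounds <- stats::qbinom(c(0.005, 0.995), n_cells, 0.5)
  expect_gte(observed_missing, bounds[1])
  expect_lte(observed_missing, bounds[2])
})

test_that("generation is deterministic: same config gives byte-identical files", {
  cfg <- study_config(n_individuals = 15, n_waves = 2, seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_staging(generate_study(cfg), d1)
  write_staging(generate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("item values respect each instrument's response range", {
  for (ins in c("PHQ-9", "PCL-5", "PSQ")) {
    b <- generate_study(study_config(
      n_individuals = 12, n_waves = 1, instruments = ins,
      covariates = character(0), item_missingness = 0, seed = 8
    ))
    defn <- instrument_definition(ins)
    expect_true(all(b$responses$numeric_value >= defn$item_min))
    expect_true(all(b$responses$numeric_value <= defn$item_max))
  }
})

test_that("a zero-count injection spec is the identity with an empty ledger", {
  b <- generate_study(study_config(n_individuals = 8, seed = 3))
  out <- inject_errors(b, error_spec(seed = 1))
  expect_identical(as.data.frame(out$bundle$individuals), as.data.frame(b$individuals))
  expect_identical(as.data.frame(out$bundle$responses), as.data.frame(b$responses))
  expect_equal(nrow(out$ledger), 0)
})

test_that("future-birth injection corrupts exactly the ledgered individuals", {
  cfg <- study_config(n_individuals = 20, seed = 6)
  b <- generate_study(cfg)
  out <- inject_errors(b, error_spec(future_birth_dates = 3, seed = 2),
    reference_date = cfg$reference_date)
  expect_equal(nrow(out$ledger), 3)
  hit <- out$bundle$individuals$individual_id %in% out$ledger$key
  expect_true(all(out$bundle$individuals$birth_date[hit] > cfg$reference_date))
  expect_true(all(out$bundle$individuals$birth_date[!hit] <= cfg$reference_date))
})

test_that("ledger size is the sum of requested counts with distinct keys", {
  cfg <- study_config(n_individuals = 30, n_waves = 2, seed = 14)
  b <- generate_study(cfg)
  out <- inject_errors(b,
    error_spec(event_before_birth = 2, null_required_ids = 2, seed = 5),
    reference_date = cfg$reference_date)
  expect_equal(nrow(out$ledger), 4)
  expect_equal(dplyr::n_distinct(out$ledger$key), 4)
})

test_that("injection conserves row counts and touches only ledgered rows", {
  cfg <- study_config(n_individuals = 25, n_waves = 2, seed = 21)
  b <- generate_study(cfg)
  out <- inject_errors(b,
    error_spec(future_birth_dates = 2, unmapped_codes = 3,
      out_of_range_items = 2, seed = 9),
    reference_date = cfg$reference_date)
  expect_equal(nrow(out$bundle$responses), nrow(b$responses))
  expect_equal(nrow(out$bundle$individuals), nrow(b$individuals))
  keys_before <- paste(b$responses$individual_id, b$responses$wave_id,
    b$responses$variable_id, sep = "::")
  changed <- which(b$responses$raw_value != out$bundle$responses$raw_value)
  expect_setequal(keys_before[changed],
    out$ledger$key[out$ledger$table == "responses"])
})

test_that("requesting more corruptions than eligible rows is fatal", {
  b <- generate_study(study_config(n_individuals = 2, seed = 4))
  expect_error(
    inject_errors(b, error_spec(null_required_ids = 5, seed = 1)),
    "shortfall"
  )
})
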
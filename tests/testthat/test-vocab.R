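test_that("local concept ids are allocated sequentially above two billion", {
  reg <- concept_registry()
  reg <- mint_local_concept(reg, "first concept", "Observation")
  expect_equal(minted_concepts(reg)$concept_id, 2000000001)

  reg <- mint_local_concept(reg, "second", "Observation")
  reg <- mint_local_concept(reg, "third", "Meas Value")
  reg <- mint_local_concept(reg, "fourth", "Measurement")
  expect_equal(minted_concepts(reg)$concept_id, 2000000004)

  # a preloaded standard id never shifts the local range
  reg2 <- register_concepts(concept_registry(),
    tibble::tibble(concept_id = 45000000, concept_name = "std",
      domain_id = "Observation", vocabulary_id = "SNOMED"))
  reg2 <- mint_local_concept(reg2, "local", "Observation")
  expect_gt(minted_concepts(reg2)$concept_id, 2000000000)
})

test_that("re-minting an existing (name, domain) pair is idempotent", {
  reg <- mint_local_concept(concept_registry(), "stress item", "Observation")
  id1 <- minted_concepts(reg)$concept_id
  expect_warning(reg <- mint_local_concept(reg, "stress item", "Observation"),
    "already minted")
  expect_equal(minted_concepts(reg)$concept_id, id1)
  expect_equal(nrow(reg$concepts), 1)
})

test_that("relationships are stored as forward/inverse pairs exactly once", {
  reg <- mint_local_concepts(concept_registry(), tibble::tibble(
    name = c("q", "a", "std-ish"), domain_id = c("Observation", "Meas Value",
      "Observation")))
  ids <- reg$concepts$concept_id
  reg <- pair_relationship(reg, ids[1], ids[3], "Maps to")
  rel <- reg$relationships
  expect_equal(nrow(rel), 2)
  expect_true(any(rel$concept_id_1 == ids[1] & rel$concept_id_2 == ids[3] &
    rel$relationship_id == "Maps to"))
  expect_true(any(rel$concept_id_1 == ids[3] & rel$concept_id_2 == ids[1] &
    rel$relationship_id == "Maps from"))

  reg <- pair_relationship(reg, ids[1], ids[3], "Maps to")  # idempotent
  expect_equal(nrow(reg$relationships), 2)

  reg <- pair_relationship(reg, ids[1], ids[2], "Has answer")
  expect_true(any(reg$relationships$concept_id_1 == ids[2] &
    reg$relationships$concept_id_2 == ids[1] &
    reg$relationships$relationship_id == "Is an answer of"))

  expect_error(pair_relationship(reg, ids[1], ids[2], "Subsumes"),
    "unknown relationship_id")

  # global pairing invariant
  inv <- c("Maps to" = "Maps from", "Maps from" = "Maps to",
    "Has answer" = "Is an answer of", "Is an answer of" = "Has answer")
  rel <- reg$relationships
  for (k in seq_len(nrow(rel))) {
    expect_true(any(rel$concept_id_1 == rel$concept_id_2[k] &
      rel$concept_id_2 == rel$concept_id_1[k] &
      rel$relationship_id == inv[[rel$relationship_id[k]]]))
  }
})

test_that("classification partitions the registry and conserves counts", {
  reg <- register_concepts(concept_registry(), base_standard_concepts())
  cls <- classify_concepts(reg)
  expect_equal(sum(cls$n_local), 0)
  expect_equal(sum(cls$n_total), nrow(reg$concepts))

  reg <- mint_local_concepts(reg, tibble::tibble(
    name = c("l1", "l2"), domain_id = c("Observation", "Meas Value")))
  cls <- classify_concepts(reg)
  expect_equal(sum(cls$n_local), 2)
  expect_equal(sum(cls$n_standard) + sum(cls$n_local), nrow(reg$concepts))
})

test_that("the fixture vocabulary reproduces the packaged composition", {
  reg <- build_fixture_vocabulary()
  expect_equal(nrow(reg$concepts), 255)
  cls <- classify_concepts(reg)
  expect_equal(sum(cls$n_standard), 227)
  expect_equal(sum(cls$n_local), 28)
  local_by_domain <- setNames(cls$n_local, cls$domain_id)
  expect_equal(unname(local_by_domain["Observation"]), 20)
  expect_equal(unname(local_by_domain["Meas Value"]), 6)
  expect_equal(unname(local_by_domain["Measurement"]), 2)
  # all local concepts are standard-flagged
  loc <- reg$concepts[reg$concepts$vocabulary_id == reg$local_vocabulary_id, ]
  expect_equal(sum(loc$standard_concept == "S"), 28)
  expect_equal(sum(cls$n_total), 255)
})

test_that("Athena-style vocabulary files round-trip losslessly", {
  reg <- build_fixture_vocabulary()
  dir <- withr::local_tempdir()
  write_vocabulary(reg, dir)
  reg2 <- load_vocabulary(dir)
  expect_equal(as.data.frame(reg2$concepts), as.data.frame(reg$concepts))
  expect_equal(as.data.frame(reg2$vocabularies), as.data.frame(reg$vocabularies))
  expect_equal(as.data.frame(reg2$relationships), as.data.frame(reg$relationships))
})

test_that("loading rejects duplicate concept ids, accepts empty files", {
  reg <- mint_local_concept(concept_registry(), "dup", "Observation")
  dir <- withr::local_tempdir()
  write_vocabulary(reg, dir)
  concept_file <- file.path(dir, "CONCEPT.csv")
  lines <- readLines(concept_file)
  writeLines(c(lines, lines[2]), concept_file)
  expect_error(load_vocabulary(dir), "duplicate concept_id.*2000000001")

  dir2 <- withr::local_tempdir()
  write_vocabulary(concept_registry(), dir2)
  reg_empty <- load_vocabulary(dir2)
  expect_equal(nrow(reg_empty$concepts), 0)
})
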
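test_that("composite totals follow the instrument scoring rules", {
  phq9 <- instrument_definition("PHQ-9")
  expect_equal(score_instrument(phq9, rep(0, 9))$total, 0)
  expect_equal(score_instrument(phq9, rep(3, 9))$total, 27)

  dass <- instrument_definition("DASS-21")
  res <- score_instrument(dass, rep(1, 21))
  expect_equal(res$total, 42)  # doubling rule
  expect_equal(res$subscales[[1]]$depression, 14)  # 2 x 7 x 1
  expect_equal(res$subscales[[1]]$anxiety, 14)
})

test_that("a missing item leaves the total absent under the default policy", {
  gad <- instrument_definition("GAD-7")
  items <- c(1, 2, NA, 0, 1, 2, 3)
  res <- score_instrument(gad, items)
  expect_true(is.na(res$total))
  expect_false(res$complete)
  expect_equal(res$n_items_missing, 1L)
  # prorating is an explicit opt-in and needs >= 80% answered
  res_pro <- score_instrument(gad, items, prorate = TRUE)
  expect_equal(res_pro$total, round(mean(items, na.rm = TRUE) * 7))
})

test_that("an out-of-range item is fatal and names the item", {
  phq9 <- instrument_definition("PHQ-9")
  expect_error(score_instrument(phq9, c(rep(0, 4), 9, rep(0, 4))), "item 5")
  res <- score_instrument(phq9, c(rep(0, 4), 9, rep(0, 4)),
    on_invalid = "treat_missing")
  expect_false(res$complete)
})

test_that("totals are monotone in any item and bounded by the score range", {
  set.seed(91)
  for (ins in c("PHQ-9", "PCL-5", "PSQ", "DASS-21")) {
    defn <- instrument_definition(ins)
    mult <- if (defn$score_rule == "sum_times_two") 2 else 1
    for (rep_i in 1:20) {
      items <- sample(defn$item_min:defn$item_max, defn$n_items, replace = TRUE)
      total <- score_instrument(defn, items)$total
      expect_gte(total, mult * defn$n_items * defn$item_min)
      expect_lte(total, mult * defn$n_items * defn$item_max)
      j <- sample(defn$n_items, 1)
      if (items[j] < defn$item_max) {
        bumped <- items; bumped[j] <- bumped[j] + 1
        expect_gte(score_instrument(defn, bumped)$total, total)
      }
    }
  }
})

test_that("wave_scores yields one result per administered instance", {
  b <- generate_study(study_config(
    n_individuals = 10, n_waves = 2, instruments = "GAD-7",
    covariates = character(0), item_missingness = 0, seed = 17
  ))
  ws <- wave_scores(b)
  expect_equal(nrow(ws), 20)
  expect_true(all(ws$complete))

  # erase all of one individual's wave-2 items: the instance disappears
  drop <- b$responses$individual_id == "IND000001" &
    b$responses$wave_id == b$waves$wave_id[2]
  b$responses <- b$responses[!drop, ]
  expect_equal(nrow(wave_scores(b)), 19)

  # erase a single item instead: the instance stays but is incomplete
  b2 <- generate_study(study_config(
    n_individuals = 10, n_waves = 2, instruments = "GAD-7",
    covariates = character(0), item_missingness = 0, seed = 17
  ))
  one <- which(b2$responses$individual_id == "IND000002" &
    b2$responses$wave_id == b2$waves$wave_id[1])[1]
  b2$responses <- b2$responses[-one, ]
  ws2 <- wave_scores(b2)
  expect_equal(nrow(ws2), 20)
  incomplete <- ws2[!ws2$complete, ]
  expect_equal(nrow(incomplete), 1)
  expect_true(is.na(incomplete$total))
})

test_that("vectorised wave scoring agrees with per-instance score_instrument", {
  b <- generate_study(study_config(
    n_individuals = 6, n_waves = 2, instruments = c("PHQ-9", "DASS-21"),
    covariates = character(0), item_missingness = 0.2, seed = 44
  ))
  ws <- wave_scores(b)
  for (k in seq_len(nrow(ws))) {
    defn <- instrument_definition(ws$instrument_id[k])
    ids <- sort(b$variables$variable_id[!is.na(b$variables$instrument_id) &
      b$variables$instrument_id == ws$instrument_id[k]])
    g <- b$responses[b$responses$individual_id == ws$individual_id[k] &
      b$responses$wave_id == ws$wave_id[k] &
      b$responses$variable_id %in% ids, ]
    ref <- score_instrument(defn, g$numeric_value[match(ids, g$variable_id)])
    expect_identical(ref$total, ws$total[k])
    expect_identical(ref$complete, ws$complete[k])
    expect_identical(ref$n_items_missing, ws$n_items_missing[k])
  }
})
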
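test_that("interval overlap has inclusive endpoints and matches brute force", {
  d <- function(day) ts_utc(sprintf("2016-01-%02d", day))
  expect_true(exposures_overlap(d(1), d(5), d(5), d(10)))   # shared endpoint
  expect_false(exposures_overlap(d(1), d(4), d(5), d(10)))
  # exhaustive: all interval pairs with endpoints in 1..6 against a
  # point-membership oracle on whole days
  for (s1 in 1:6) for (e1 in s1:6) for (s2 in 1:6) for (e2 in s2:6) {
    brute <- length(intersect(seq(s1, e1), seq(s2, e2))) > 0
    expect_equal(exposures_overlap(d(s1), d(e1), d(s2), d(e2)), brute)
    # symmetry
    expect_equal(exposures_overlap(d(s2), d(e2), d(s1), d(e1)), brute)
  }
  # reflexivity
  expect_true(exposures_overlap(d(2), d(3), d(2), d(3)))
})

test_that("concomitant pairs: basic detection and trigger timing", {
  sets <- resolved_sets()
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    exposures = list(
      list(1L, 1120, "2016-01-01T08:00:00Z", "2016-01-31T08:00:00Z"),
      list(1L, 1131, "2016-01-10T09:00:00Z", "2016-01-20T09:00:00Z")))
  pairs <- find_concomitant_pairs(store, sets$warfarin, sets$antidepressants)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$trigger_datetime, ts_utc("2016-01-10 09:00:00"))
  expect_equal(pairs$object_exposure_id, 1L)
  expect_equal(pairs$precipitant_exposure_id, 2L)
})

test_that("same-start exposures with different dose directions are separate pairs", {
  sets <- resolved_sets()
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "FEMALE")),
    exposures = list(
      list(1L, 1001, "2016-01-10T08:00:00Z", "2016-01-25T08:00:00Z",
           dir = "take in the morning"),
      list(1L, 1001, "2016-01-10T08:00:00Z", "2016-01-20T08:00:00Z",
           dir = "take at bedtime"),
      list(1L, 1011, "2016-01-12T09:00:00Z", "2016-01-18T09:00:00Z")))
  pairs <- find_concomitant_pairs(store, sets$citalopram,
                                  sets$qt_prolonging_agents)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$object_exposure_id, c(1L, 2L))
})

test_that("pair detection equals a nested-loop scan on a random population", {
  sets <- resolved_sets()
  store <- generate_random(generator_spec(seed = 99, n_persons = 50))
  pairs <- find_concomitant_pairs(store, sets$warfarin, sets$antidepressants)
  dx <- store$drug_exposure
  brute <- 0L
  for (i in seq_len(nrow(dx))) for (j in seq_len(nrow(dx))) {
    if (i == j || dx$person_id[i] != dx$person_id[j]) next
    if (!dx$drug_concept_id[i] %in% sets$warfarin$member_concept_ids) next
    if (!dx$drug_concept_id[j] %in% sets$antidepressants$member_concept_ids) next
    if (dx$start_datetime[i] <= dx$end_datetime[j] &&
        dx$start_datetime[j] <= dx$end_datetime[i]) brute <- brute + 1L
  }
  expect_equal(nrow(pairs), brute)
  # row order of the input must not matter
  shuffled <- store
  set.seed(1)
  shuffled$drug_exposure <- dx[sample(nrow(dx)), , drop = FALSE]
  pairs2 <- find_concomitant_pairs(shuffled, sets$warfarin,
                                   sets$antidepressants)
  expect_equal(nrow(pairs2), nrow(pairs))
  expect_equal(pairs2, pairs, ignore_attr = TRUE)
})

test_that("latest_measurement takes the most recent value, never the future", {
  sets <- resolved_sets()
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    measurements = list(
      list(1L, 2001, "2016-01-01T06:00:00Z", 4.0, "mEq/L"),
      list(1L, 2001, "2016-01-05T06:00:00Z", 3.2, "mmol/L"),
      list(1L, 2001, "2016-01-07T06:00:00Z", 5.5, "mEq/L")))
  got <- latest_measurement(store, 1L, sets$serum_potassium_lab,
                            ts_utc("2016-01-06"), 30)
  expect_equal(got$value, 3.2)
  expect_equal(got$unit, "mEq/L")  # mmol/L normalized 1:1
  # only a future value -> MISSING
  expect_null(latest_measurement(store, 1L, sets$serum_potassium_lab,
                                 ts_utc("2015-12-31"), 30))
  # outside the lookback window -> MISSING
  expect_null(latest_measurement(store, 1L, sets$serum_potassium_lab,
                                 ts_utc("2016-03-01"), 3))
  expect_error(latest_measurement(store, 1L, sets$serum_potassium_lab,
                                  ts_utc("2016-01-06"), 0), "positive")
})

test_that("latest_measurement agrees with a full-scan oracle on random data", {
  sets <- resolved_sets()
  set.seed(23)
  n <- 200L
  taken <- ts_utc("2016-01-01") + round(runif(n, 0, 80 * 86400))
  ms <- data.frame(measurement_id = seq_len(n), person_id = 1L,
                   measurement_concept_id = 2001, taken_datetime = taken,
                   value = round(runif(n, 3, 6), 2), unit = "mEq/L")
  v <- bundled_vocabulary()
  store <- patient_store(
    person = data.frame(person_id = 1L, birth_date = as.Date("1950-06-15"),
                        sex = "MALE", ethnicity = NA),
    measurement = ms, concept = v$concept,
    concept_ancestor = v$concept_ancestor)
  for (probe in 1:20) {
    as_of <- ts_utc("2016-01-01") + round(runif(1, 0, 90 * 86400))
    lb <- sample(c(3, 10, 30), 1)
    got <- latest_measurement(store, 1L, sets$serum_potassium_lab, as_of, lb)
    ok <- ms$taken_datetime <= as_of & ms$taken_datetime >= as_of - lb * 86400
    if (!any(ok)) expect_null(got)
    else {
      cand <- ms[ok, ]
      cand <- cand[order(cand$taken_datetime, cand$measurement_id), ]
      expect_equal(got$value, cand$value[nrow(cand)])
    }
  }
})

test_that("age is completed years by the anniversary convention", {
  expect_equal(age_at(as.Date("1948-01-15"), ts_utc("2016-01-15")), 68L)
  expect_equal(age_at(as.Date("1948-01-15"), ts_utc("2016-01-14")), 67L)
  expect_error(age_at(as.Date("1948-01-15"), ts_utc("1940-01-01")), "precedes")
  # random pairs against a calendar oracle (count anniversaries <= as_of)
  set.seed(5)
  for (i in 1:40) {
    birth <- as.Date(sprintf("%d-%02d-%02d", sample(1930:1990, 1),
                             sample(1:12, 1), sample(1:28, 1)))
    as_of <- birth + sample(0:30000, 1)
    oracle <- length(seq(birth, as_of, by = "year")) - 1L
    expect_equal(age_at(birth, as.POSIXct(as_of, tz = "UTC")), oracle)
  }
})

test_that("condition lookup distinguishes history-of from active diagnosis", {
  sets <- resolved_sets()
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    conditions = list(
      list(1L, 3001, "2010-03-01"),                  # MI, open-ended
      list(1L, 3002, "2016-01-01", "2016-01-10")))   # sepsis, resolved
  at <- ts_utc("2016-02-01")
  expect_true(has_active_condition(store, 1L, sets$myocardial_infarction, at,
                                   "EVER"))
  expect_true(has_active_condition(store, 1L, sets$sepsis, at, "EVER"))
  expect_false(has_active_condition(store, 1L, sets$sepsis, at, "ACTIVE"))
  expect_false(has_active_condition(store, 1L, sets$heart_failure, at, "EVER"))
  # a future-dated condition is never visible
  expect_false(has_active_condition(store, 1L, sets$myocardial_infarction,
                                    ts_utc("2009-01-01"), "EVER"))
})

test_that("discontinuation requires a recent end and no ongoing exposure", {
  sets <- resolved_sets()
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    exposures = list(
      list(1L, 1030, "2016-01-01T08:00:00Z", "2016-01-10T08:00:00Z")))
  expect_true(detect_discontinuation(store, 1L, sets$clonidine,
                                     ts_utc("2016-01-12"), 7))
  expect_false(detect_discontinuation(store, 1L, sets$clonidine,
                                      ts_utc("2016-01-05"), 7))  # ongoing
  expect_false(detect_discontinuation(store, 1L, sets$clonidine,
                                      ts_utc("2016-02-15"), 7))  # too old
  # a second ongoing exposure suppresses the withdrawal signal
  store2 <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    exposures = list(
      list(1L, 1030, "2016-01-01T08:00:00Z", "2016-01-10T08:00:00Z"),
      list(1L, 1030, "2016-01-09T08:00:00Z", "2016-01-20T08:00:00Z")))
  expect_false(detect_discontinuation(store2, 1L, sets$clonidine,
                                      ts_utc("2016-01-12"), 7))
})

test_that("build_context populates exactly the declared factors, deterministically", {
  sets <- resolved_sets()
  tree <- bundled_trees()$citalopram_qt
  store <- quick_store(
    persons = list(list(1L, "1946-01-01", "FEMALE")),
    exposures = list(
      list(1L, 1001, "2016-01-10T08:00:00Z", "2016-01-25T08:00:00Z",
           dose = 20, unit = "mg/day"),
      list(1L, 1011, "2016-01-12T09:00:00Z", "2016-01-18T09:00:00Z"),
      list(1L, 1021, "2016-01-11T08:00:00Z", "2016-01-15T08:00:00Z")),
    measurements = list(
      list(1L, 2001, "2016-01-11T06:00:00Z", 3.2, "mEq/L")))
  pair <- find_concomitant_pairs(store, sets$citalopram,
                                 sets$qt_prolonging_agents)
  ctx <- build_context(store, pair, tree, context_config(), sets)
  declared <- vapply(tree$factors, `[[`, "", "name")
  expect_identical(names(ctx$factor_values), declared)
  expect_true(ctx$factor_values$female_sex)
  expect_equal(ctx$age_years, 70L)
  expect_true(ctx$factor_values$age_ge_68)
  expect_true(ctx$factor_values$k_low)          # K 3.2 within 3-day window
  expect_true(ctx$factor_values$loop_diuretic)  # furosemide overlapping
  expect_true(is.na(ctx$factor_values$qtc))     # no ECG -> MISSING
  expect_equal(ctx$factor_values$citalopram_dose, 20)
  expect_equal(ctx$factor_values$n_risk, 4)     # female, age, K, loop diuretic
  # provenance points at the potassium measurement
  expect_equal(ctx$provenance$k_low, 1L)
  # purity: same pair twice -> identical context
  ctx2 <- build_context(store, pair, tree, context_config(), sets)
  expect_identical(ctx2, ctx)
})

test_that("a person with no labs gets MISSING lab factors", {
  sets <- resolved_sets()
  tree <- bundled_trees()$citalopram_qt
  store <- quick_store(
    persons = list(list(1L, "1980-01-01", "MALE")),
    exposures = list(
      list(1L, 1001, "2016-01-10T08:00:00Z", "2016-01-25T08:00:00Z"),
      list(1L, 1011, "2016-01-12T09:00:00Z", "2016-01-18T09:00:00Z")))
  pair <- find_concomitant_pairs(store, sets$citalopram,
                                 sets$qt_prolonging_agents)
  ctx <- build_context(store, pair, tree, context_config(), sets)
  expect_true(is.na(ctx$factor_values$qtc))
  expect_true(is.na(ctx$factor_values$k_low))
  expect_true(is.na(ctx$factor_values$citalopram_dose))
})
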
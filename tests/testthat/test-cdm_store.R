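test_that("a written store reads back field-for-field", {
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "FEMALE"),
                   list(2L, "1980-01-02", "MALE")),
    exposures = list(
      list(1L, 1120, "2016-01-01T08:00:00Z", "2016-01-20T08:00:00Z",
           dose = 5, unit = "mg/day", dir = "take at bedtime"),
      list(2L, 1171, "2016-02-01", "2016-02-10", route = "TOPICAL")),
    measurements = list(list(1L, 2001, "2016-01-03T06:30:00Z", 4.2, "mEq/L")),
    conditions = list(list(1L, 3003, "2010-05-01"),
                      list(2L, 3002, "2016-01-01", "2016-01-20")),
    visits = list(list(1L, "2016-01-01T00:00:00Z", "2016-01-05T00:00:00Z",
                       "INPATIENT")))
  dir <- withr::local_tempdir()
  write_patient_store(store, dir)
  back <- read_patient_store(dir)
  for (nm in names(store))
    expect_equal(back[[nm]], store[[nm]], info = nm)
  # date-only input was promoted to midnight UTC
  expect_equal(format(back$drug_exposure$start_datetime[2],
                      "%H:%M", tz = "UTC"), "00:00")
})

test_that("empty tables load to an empty store and missing files are fatal", {
  dir <- withr::local_tempdir()
  write_patient_store(empty_patient_store(), dir)
  store <- read_patient_store(dir)
  expect_equal(nrow(store$person), 0L)
  expect_equal(nrow(store$drug_exposure), 0L)
  file.remove(file.path(dir, "measurement.csv"))
  expect_error(read_patient_store(dir), "measurement.csv")
})

test_that("dangling references abort the load with an integrity error", {
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    exposures = list(list(99L, 1120, "2016-01-01", "2016-01-05")))
  dir <- withr::local_tempdir()
  write_patient_store(store, dir)
  expect_error(read_patient_store(dir), "integrity")
})

test_that("validate_store returns violations instead of raising", {
  good <- quick_store(
    persons = list(list(1L, "1950-06-15", "FEMALE")),
    exposures = list(list(1L, 1120, "2016-01-10", "2016-01-20")))
  expect_equal(nrow(validate_store(good)), 0L)

  reversed <- good
  reversed$drug_exposure$end_datetime <- ts_utc("2016-01-05")
  v <- validate_store(reversed)
  expect_true(any(v$entity == "drug_exposure" & grepl("start <= end", v$rule)))

  late_birth <- good
  late_birth$person$birth_date <- as.Date("2016-06-01")
  v <- validate_store(late_birth)
  expect_true(any(v$entity == "person" & grepl("birth precedes", v$rule)))

  cyclic <- good
  cyclic$concept_ancestor <- rbind(
    cyclic$concept_ancestor,
    data.frame(ancestor_concept_id = c(1042, 1041),
               descendant_concept_id = c(1041, 1042)))
  v <- validate_store(cyclic)
  expect_true(any(v$rule == "acyclic"))
})

test_that("visit filtering keeps a 24 h visit at a 24 h threshold", {
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    visits = list(
      list(1L, "2016-01-01T08:00:00Z", "2016-01-02T08:00:00Z", "UNKNOWN"),
      list(1L, "2016-01-05T08:00:00Z", "2016-01-06T07:00:00Z", "UNKNOWN"),
      list(1L, "2016-01-10T08:00:00Z", "2016-01-20T08:00:00Z", "INPATIENT")))
  out <- filter_visits_min_duration(store, 24)
  expect_equal(out$visit_occurrence$visit_id, c(1L, 3L))  # 23 h visit dropped
  # idempotent
  twice <- filter_visits_min_duration(out, 24)
  expect_equal(twice$visit_occurrence, out$visit_occurrence)
  # zero threshold is the identity
  ident <- filter_visits_min_duration(store, 0)
  expect_equal(ident$visit_occurrence, store$visit_occurrence)
  # original untouched
  expect_equal(nrow(store$visit_occurrence), 3L)
  expect_error(filter_visits_min_duration(store, -1), "non-negative")
})

test_that("event filtering to retained visits is optional and off by default", {
  store <- quick_store(
    persons = list(list(1L, "1950-06-15", "MALE")),
    exposures = list(
      list(1L, 1120, "2016-01-10T12:00:00Z", "2016-01-12T12:00:00Z"),
      list(1L, 1171, "2016-02-01T12:00:00Z", "2016-02-02T12:00:00Z")),
    visits = list(list(1L, "2016-01-10T00:00:00Z", "2016-01-15T00:00:00Z",
                       "INPATIENT")))
  default <- filter_visits_min_duration(store, 24)
  expect_equal(nrow(default$drug_exposure), 2L)
  strict <- filter_visits_min_duration(store, 24, events_within_visits = TRUE)
  expect_equal(strict$drug_exposure$exposure_id, 1L)
})

test_that("unknown extra columns are ignored with a warning", {
  dir <- withr::local_tempdir()
  write_patient_store(empty_patient_store(), dir)
  p <- read.csv(file.path(dir, "person.csv"))
  p$bogus_column <- character(0)
  write.csv(p, file.path(dir, "person.csv"), row.names = FALSE)
  expect_warning(read_patient_store(dir), "bogus_column")
})
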
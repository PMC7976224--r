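# Synthetic population generators. All three generators emit stores that
# carry the bundled vocabulary and pass validate_store() with zero
# violations; that gate is part of the test suite.

.ts <- function(x) .parse_ts(x)

# ingredient-level (leaf) members of a resolved set, i.e. members with no
# descendants in the ancestry; the generator prescribes ingredients, not
# drug-class concepts
.leaf_members <- function(resolved, ancestry) {
  m <- resolved$member_concept_ids
  sort(setdiff(m, ancestry$ancestor_concept_id))
}

.rep_member <- function(resolved, ancestry) .leaf_members(resolved, ancestry)[1L]

# mutable row accumulator for building stores
.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$person <- list(); env$drug_exposure <- list(); env$measurement <- list()
  env$condition_occurrence <- list(); env$visit_occurrence <- list()
  env$next_exposure <- 1L; env$next_measurement <- 1L; env$next_visit <- 1L
  env
}

.add_person <- function(b, person_id, birth, sex, ethnicity = NA) {
  b$person[[length(b$person) + 1L]] <- data.frame(
    person_id = person_id, birth_date = as.Date(birth), sex = sex,
    ethnicity = ethnicity, stringsAsFactors = FALSE)
  person_id
}

.add_exposure <- function(b, person_id, concept, start, end, dose = NA,
                          dose_unit = NA, route = "ORAL", direction = NA) {
  id <- b$next_exposure; b$next_exposure <- id + 1L
  b$drug_exposure[[length(b$drug_exposure) + 1L]] <- data.frame(
    exposure_id = id, person_id = person_id, drug_concept_id = concept,
    start_datetime = .ts(start), end_datetime = .ts(end),
    daily_dose_value = dose, daily_dose_unit = dose_unit, route = route,
    dose_direction = direction, stringsAsFactors = FALSE)
  id
}

.add_measurement <- function(b, person_id, concept, taken, value, unit) {
  id <- b$next_measurement; b$next_measurement <- id + 1L
  b$measurement[[length(b$measurement) + 1L]] <- data.frame(
    measurement_id = id, person_id = person_id,
    measurement_concept_id = concept, taken_datetime = .ts(taken),
    value = value, unit = unit, stringsAsFactors = FALSE)
  id
}

.add_condition <- function(b, person_id, concept, start, end = NA) {
  b$condition_occurrence[[length(b$condition_occurrence) + 1L]] <- data.frame(
    person_id = person_id, condition_concept_id = concept,
    start_date = as.Date(start),
    end_date = if (is.na(end)) as.Date(NA) else as.Date(end),
    stringsAsFactors = FALSE)
  invisible(NULL)
}

.add_visit <- function(b, person_id, start, end, kind = "UNKNOWN") {
  id <- b$next_visit; b$next_visit <- id + 1L
  b$visit_occurrence[[length(b$visit_occurrence) + 1L]] <- data.frame(
    visit_id = id, person_id = person_id, start_datetime = .ts(start),
    end_datetime = .ts(end), visit_kind = kind, stringsAsFactors = FALSE)
  id
}

.build_store <- function(b) {
  v <- bundled_vocabulary()
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  patient_store(person = bind(b$person), drug_exposure = bind(b$drug_exposure),
                measurement = bind(b$measurement),
                condition_occurrence = bind(b$condition_occurrence),
                visit_occurrence = bind(b$visit_occurrence),
                concept = v$concept, concept_ancestor = v$concept_ancestor)
}

#' Generate the fixed-census validation population
#'
#' Builds the bundled synthetic validation population: 93 persons carrying
#' exactly 208 drug exposures, 24 laboratory measurements and 12 condition
#' occurrences. For each of the eight DDI algorithms it contains at least
#' one positive scenario (a genuine overlapping co-exposure with the
#' context events its tree consumes) and one negative control
#' (non-overlapping exposures to the same drug pair that must not
#' trigger), including a same-start-timestamp duplicate citalopram pair
#' differing only in dose direction, which must be counted as two alerts.
#' The remaining persons carry non-interacting background exposures and
#' normal potassium values that pad the census to its fixed totals. The
#' population is fully deterministic: the census and content are identical
#' for every seed.
#'
#' @param seed Integer; accepted for interface uniformity with the other
#'   generators (the population is deterministic by construction).
#' @return A `patient_store`.
#' @export
generate_validation_population <- function(seed = 1L) {
  b <- .new_builder()
  base <- empty_patient_store()
  pid <- 0L
  np <- function(birth, sex) {
    pid <<- pid + 1L
    .add_person(b, pid, birth, sex)
  }

  # -- citalopram / QT prolonging agent: positive (two citalopram orders
  #    sharing a start timestamp with different dose directions -> 2 alerts)
  p <- np("1947-06-01", "FEMALE")  # 68 at trigger
  .add_exposure(b, p, 1001, "2016-01-10T08:00:00Z", "2016-01-25T08:00:00Z",
                dose = 20, dose_unit = "mg/day",
                direction = "take one tablet in the morning")
  .add_exposure(b, p, 1001, "2016-01-10T08:00:00Z", "2016-01-20T08:00:00Z",
                dose = 20, dose_unit = "mg/day",
                direction = "take one tablet at bedtime")
  .add_exposure(b, p, 1011, "2016-01-12T09:00:00Z", "2016-01-18T09:00:00Z")
  .add_measurement(b, p, 2002, "2016-01-11T10:00:00Z", 462, "ms")
  .add_measurement(b, p, 2001, "2016-01-11T10:00:00Z", 4.1, "mEq/L")
  # negative control: no overlap
  p <- np("1960-03-10", "MALE")
  .add_exposure(b, p, 1001, "2016-01-01T08:00:00Z", "2016-01-05T08:00:00Z")
  .add_exposure(b, p, 1012, "2016-01-10T08:00:00Z", "2016-01-15T08:00:00Z")

  # -- clonidine / beta-blocker: withdrawal under continued nonselective BB
  p <- np("1955-09-20", "MALE")
  .add_exposure(b, p, 1030, "2016-01-05T08:00:00Z", "2016-01-12T08:00:00Z")
  .add_exposure(b, p, 1046, "2016-01-05T08:00:00Z", "2016-01-20T08:00:00Z")
  p <- np("1970-11-02", "FEMALE")
  .add_exposure(b, p, 1030, "2016-01-05T08:00:00Z", "2016-01-08T08:00:00Z")
  .add_exposure(b, p, 1042, "2016-01-10T08:00:00Z", "2016-01-20T08:00:00Z")

  # -- epinephrine / beta-blocker: anaphylaxis under nonselective BB
  p <- np("1980-02-14", "FEMALE")
  .add_exposure(b, p, 1060, "2016-02-01T09:00:00Z", "2016-02-01T10:00:00Z",
                dose = 0.3, dose_unit = "mg/day", route = "IV")
  .add_exposure(b, p, 1046, "2016-01-25T08:00:00Z", "2016-02-10T08:00:00Z")
  .add_condition(b, p, 3010, "2016-02-01")
  p <- np("1975-07-07", "MALE")
  .add_exposure(b, p, 1060, "2016-02-01T09:00:00Z", "2016-02-01T10:00:00Z",
                route = "IV")
  .add_exposure(b, p, 1043, "2016-02-05T08:00:00Z", "2016-02-15T08:00:00Z")

  # -- fluconazole / opioid: inpatient low-dose fluconazole -> filtered
  p <- np("1965-04-18", "MALE")
  .add_exposure(b, p, 1081, "2016-03-01T08:00:00Z", "2016-03-10T08:00:00Z",
                dose = 30, dose_unit = "mg/day")
  .add_exposure(b, p, 1070, "2016-03-02T08:00:00Z", "2016-03-09T08:00:00Z",
                dose = 100, dose_unit = "mg/day")
  .add_visit(b, p, "2016-02-28T12:00:00Z", "2016-03-08T12:00:00Z", "INPATIENT")
  p <- np("1958-12-30", "FEMALE")
  .add_exposure(b, p, 1081, "2016-03-01T08:00:00Z", "2016-03-05T08:00:00Z")
  .add_exposure(b, p, 1070, "2016-03-10T08:00:00Z", "2016-03-15T08:00:00Z")

  # -- immunosuppressant / fluconazole: high systemic dose
  p <- np("1972-08-25", "MALE")
  .add_exposure(b, p, 1091, "2016-01-20T08:00:00Z", "2016-02-20T08:00:00Z",
                dose = 4, dose_unit = "mg/day")
  .add_exposure(b, p, 1070, "2016-02-01T08:00:00Z", "2016-02-10T08:00:00Z",
                dose = 400, dose_unit = "mg/day")
  p <- np("1983-01-05", "FEMALE")
  .add_exposure(b, p, 1091, "2016-01-01T08:00:00Z", "2016-01-10T08:00:00Z")
  .add_exposure(b, p, 1070, "2016-01-15T08:00:00Z", "2016-01-20T08:00:00Z")

  # -- potassium / potassium-sparing diuretic: recent K >= 5.0
  p <- np("1950-10-12", "FEMALE")
  .add_exposure(b, p, 1099, "2016-02-10T08:00:00Z", "2016-02-25T08:00:00Z")
  .add_exposure(b, p, 1111, "2016-02-12T08:00:00Z", "2016-02-20T08:00:00Z")
  .add_measurement(b, p, 2001, "2016-02-11T07:00:00Z", 5.4, "mEq/L")
  p <- np("1968-06-03", "MALE")
  .add_exposure(b, p, 1099, "2016-02-01T08:00:00Z", "2016-02-05T08:00:00Z")
  .add_exposure(b, p, 1111, "2016-02-10T08:00:00Z", "2016-02-18T08:00:00Z")

  # -- warfarin / antidepressant: serotonergic SSRI with NSAID co-risk
  p <- np("1945-05-22", "MALE")
  .add_exposure(b, p, 1120, "2016-01-01T08:00:00Z", "2016-03-31T08:00:00Z",
                dose = 5, dose_unit = "mg/day")
  .add_exposure(b, p, 1131, "2016-02-01T08:00:00Z", "2016-02-28T08:00:00Z")
  .add_exposure(b, p, 1171, "2016-02-01T08:00:00Z", "2016-02-14T08:00:00Z")
  p <- np("1979-09-09", "FEMALE")
  .add_exposure(b, p, 1120, "2016-01-01T08:00:00Z", "2016-01-10T08:00:00Z")
  .add_exposure(b, p, 1131, "2016-01-15T08:00:00Z", "2016-01-30T08:00:00Z")

  # -- warfarin / salicylate: aspirin with active thromboembolic indication
  p <- np("1952-03-17", "MALE")
  .add_exposure(b, p, 1120, "2016-02-01T08:00:00Z", "2016-02-28T08:00:00Z",
                dose = 5, dose_unit = "mg/day")
  .add_exposure(b, p, 1180, "2016-02-05T08:00:00Z", "2016-02-20T08:00:00Z",
                dose = 81, dose_unit = "mg/day")
  .add_condition(b, p, 3031, "2016-01-01")
  p <- np("1961-07-29", "FEMALE")
  .add_exposure(b, p, 1120, "2016-02-01T08:00:00Z", "2016-02-10T08:00:00Z")
  .add_exposure(b, p, 1211, "2016-02-15T08:00:00Z", "2016-02-28T08:00:00Z")

  # -- padding to the fixed census: 77 background persons, 174 background
  #    exposures of non-interacting drugs, 21 normal potassium values, 10
  #    hypertension diagnoses, a few visits of varying duration
  bg_drugs <- c(1021, 1171, 1191, 1201, 1172, 1022, 1192, 1202, 1114)
  n_scenario <- pid
  for (i in seq_len(93L - n_scenario)) {
    sex <- if (i %% 2 == 0) "FEMALE" else "MALE"
    birth <- as.Date("1950-01-01") + ((i * 157L) %% 16000L)
    p <- np(format(birth), sex)
    n_exp <- if (i <= 20L) 3L else 2L
    for (k in seq_len(n_exp)) {
      drug <- bg_drugs[((i + k) %% length(bg_drugs)) + 1L]
      start <- as.Date("2016-01-01") + ((i * 3L + k * 11L) %% 80L)
      .add_exposure(b, p, drug,
                    paste0(format(start), "T08:00:00Z"),
                    paste0(format(start + 5L + (k %% 7L)), "T08:00:00Z"))
    }
    if (i <= 21L)
      .add_measurement(b, p, 2001,
                       paste0(format(as.Date("2016-01-05") + i), "T06:00:00Z"),
                       round(3.8 + 0.05 * (i %% 10), 2), "mEq/L")
    if (i <= 10L)
      .add_condition(b, p, 3004, format(as.Date("2010-01-01") + i * 30L))
    if (i <= 6L)
      .add_visit(b, p,
                 paste0(format(as.Date("2016-01-10") + i), "T08:00:00Z"),
                 paste0(format(as.Date("2016-01-10") + i +
                                 (if (i %% 2 == 0) 3L else 0L)),
                        if (i %% 2 == 0) "T08:00:00Z" else "T18:00:00Z"),
                 kind = if (i %% 2 == 0) "INPATIENT" else "OUTPATIENT")
  }
  .build_store(b)
}

#' Specification for a randomized synthetic population
#'
#' @param seed Integer RNG seed; equal specs produce structurally equal
#'   stores.
#' @param n_persons Number of persons.
#' @param mean_exposures,mean_measurements,mean_conditions,mean_visits
#'   Per-person Poisson means for background event counts.
#' @param prevalence Named numeric probabilities in `[0, 1]`:
#'   `female` (sex), `co_exposure` (person receives a deliberate
#'   overlapping interacting drug pair for a randomly chosen DDI; at 0 the
#'   background drug pool contains no interacting-pair members, so no DDI
#'   can trigger), `context_drug` (an additional context-modifying drug
#'   such as a loop diuretic or NSAID), `condition` reserved via
#'   `mean_conditions`.
#' @param date_range Two dates bounding all event times.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed, n_persons, mean_exposures = 5,
                           mean_measurements = 2, mean_conditions = 1,
                           mean_visits = 1,
                           prevalence = c(female = 0.535, co_exposure = 0.3,
                                          context_drug = 0.3),
                           date_range = as.Date(c("2016-01-01",
                                                  "2016-03-31"))) {
  stopifnot(n_persons >= 0, mean_exposures >= 0, mean_measurements >= 0,
            mean_conditions >= 0, mean_visits >= 0,
            all(prevalence >= 0 & prevalence <= 1),
            length(date_range) == 2L)
  structure(list(seed = as.integer(seed), n_persons = as.integer(n_persons),
                 mean_exposures = mean_exposures,
                 mean_measurements = mean_measurements,
                 mean_conditions = mean_conditions, mean_visits = mean_visits,
                 prevalence = prevalence, date_range = as.Date(date_range)),
            class = "generator_spec")
}

#' Generate a randomized synthetic population
#'
#' Draws a population per the spec: per-person event counts are Poisson
#' with the stated means, background drugs come from a pool of concepts
#' that belong to no DDI drug pair (so deliberate co-exposures, injected
#' with probability `co_exposure` per person for a uniformly chosen DDI,
#' are the only source of alerts besides context-modifying drugs),
#' laboratory values are Gaussian around clinically typical levels
#' (potassium ~ N(4.3, 0.45) mEq/L, QTc ~ N(435, 30) ms), and conditions
#' and visits are drawn uniformly over the bundled condition pool and the
#' date range. Deterministic given the seed.
#'
#' @param spec A `generator_spec`.
#' @return A `patient_store`.
#' @export
generate_random <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  b <- .new_builder()
  base <- empty_patient_store()
  sets <- resolve_concept_sets(bundled_concept_sets(), base)
  anc <- base$concept_ancestor
  trees <- bundled_trees()
  ddi_ids <- names(trees)
  bg_drugs <- c(1021, 1022, 1171, 1172, 1191, 1192, 1201, 1202, 1114)
  context_drugs <- c(1021, 1171, 1180, 1191, 1201)
  cond_pool <- c(3001, 3002, 3003, 3004, 3010, 3021, 3022, 3031, 3032, 3033)
  d0 <- spec$date_range[1L]; d1 <- spec$date_range[2L]
  span <- as.integer(d1 - d0)
  prev <- function(nm) unname(spec$prevalence[nm]) %||% 0
  pick1 <- function(x) x[sample.int(length(x), 1L)]
  rand_start <- function() d0 + sample.int(max(span, 1L), 1L) - 1L
  rand_ts <- function(day) paste0(format(day), sprintf("T%02d:%02d:00Z",
                                  sample(0:23, 1L), sample(0:59, 1L)))
  add_rand_exposure <- function(p, concept, day = rand_start(),
                                dur = sample(3:21, 1L), dose = NA,
                                unit = NA, route = "ORAL") {
    .add_exposure(b, p, concept, rand_ts(day), rand_ts(day + dur),
                  dose = dose, dose_unit = unit, route = route)
  }
  for (i in seq_len(spec$n_persons)) {
    sex <- if (runif(1) < prev("female")) "FEMALE" else "MALE"
    birth <- as.Date("1930-01-01") + sample.int(23000L, 1L)
    p <- .add_person(b, i, birth, sex)
    for (k in seq_len(rpois(1L, spec$mean_exposures)))
      add_rand_exposure(p, sample(bg_drugs, 1L))
    if (runif(1) < prev("co_exposure")) {
      tree <- trees[[sample(ddi_ids, 1L)]]
      obj <- .leaf_members(sets[[tree$object_set]], anc)
      prec <- .leaf_members(sets[[tree$precipitant_set]], anc)
      day <- rand_start()
      add_rand_exposure(p, pick1(obj), day = day,
                        dur = sample(5:28, 1L),
                        dose = sample(c(NA, 5, 20, 40, 100, 200, 400), 1L),
                        unit = "mg/day")
      add_rand_exposure(p, pick1(prec), day = day + sample(0:4, 1L),
                        dur = sample(3:21, 1L),
                        dose = sample(c(NA, 10, 25, 81, 150, 325, 3250), 1L),
                        unit = "mg/day",
                        route = sample(c("ORAL", "ORAL", "ORAL", "IV",
                                         "TOPICAL", "OPHTHALMIC"), 1L))
    }
    if (runif(1) < prev("context_drug"))
      add_rand_exposure(p, sample(context_drugs, 1L))
    for (k in seq_len(rpois(1L, spec$mean_measurements))) {
      if (runif(1) < 0.8)
        .add_measurement(b, p, 2001, rand_ts(rand_start()),
                         round(stats::rnorm(1, 4.3, 0.45), 2), "mEq/L")
      else
        .add_measurement(b, p, 2002, rand_ts(rand_start()),
                         round(stats::rnorm(1, 435, 30)), "ms")
    }
    for (k in seq_len(rpois(1L, spec$mean_conditions))) {
      start <- d0 - sample.int(2000L, 1L)
      .add_condition(b, p, sample(cond_pool, 1L), start,
                     end = if (runif(1) < 0.3) format(start + sample.int(60L, 1L))
                           else NA)
    }
    for (k in seq_len(rpois(1L, spec$mean_visits))) {
      vstart <- rand_ts(rand_start())
      hours <- sample(c(4, 8, 36, 120), 1L)
      .add_visit(b, p, vstart,
                 format(.ts(vstart) + hours * 3600, "%Y-%m-%dT%H:%M:%SZ"),
                 kind = sample(c("INPATIENT", "OUTPATIENT", "UNKNOWN"), 1L))
    }
  }
  .build_store(b)
}
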
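#' @importFrom utils read.csv write.csv head
#' @importFrom stats rpois runif setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.sex_levels <- c("FEMALE", "MALE")
.vocab_levels <- c("RXNORM", "LOINC", "SNOMED")
.route_levels <- c("ORAL", "IV", "TOPICAL", "OPHTHALMIC", "TRANSDERMAL",
                   "LOCAL_INJECTION", "OTHER")
.visit_kind_levels <- c("INPATIENT", "OUTPATIENT", "UNKNOWN")

# All event times are timestamps at minute resolution in UTC; date-only
# inputs are promoted to midnight. Duplicate-timestamp counting rules rely
# on exact timestamp equality, so no timezone arithmetic is ever applied.
.parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  x <- as.character(x)
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    y <- gsub("T", " ", sub("Z$", "", x[ok]))
    y[!grepl(" ", y)] <- paste(y[!grepl(" ", y)], "00:00:00")
    parsed <- as.POSIXct(y, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    retry <- is.na(parsed)
    if (any(retry))
      parsed[retry] <- as.POSIXct(y[retry], tz = "UTC", format = "%Y-%m-%d %H:%M")
    out[ok] <- parsed
  }
  out
}

.parse_date <- function(x) as.Date(as.character(x), format = "%Y-%m-%d")

.format_ts <- function(x) ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))

.store_schemas <- list(
  person = c(person_id = "integer", birth_date = "date", sex = "character",
             ethnicity = "character"),
  drug_exposure = c(exposure_id = "integer", person_id = "integer",
                    drug_concept_id = "integer", start_datetime = "timestamp",
                    end_datetime = "timestamp", daily_dose_value = "numeric",
                    daily_dose_unit = "character", route = "character",
                    dose_direction = "character"),
  measurement = c(measurement_id = "integer", person_id = "integer",
                  measurement_concept_id = "integer",
                  taken_datetime = "timestamp", value = "numeric",
                  unit = "character"),
  condition_occurrence = c(person_id = "integer", condition_concept_id = "integer",
                           start_date = "date", end_date = "date"),
  visit_occurrence = c(visit_id = "integer", person_id = "integer",
                       start_datetime = "timestamp", end_datetime = "timestamp",
                       visit_kind = "character"),
  concept = c(concept_id = "integer", code = "character",
              vocabulary = "character", name = "character"),
  concept_ancestor = c(ancestor_concept_id = "integer",
                       descendant_concept_id = "integer")
)

.coerce_table <- function(df, table) {
  schema <- .store_schemas[[table]]
  extra <- setdiff(names(df), names(schema))
  if (length(extra))
    warning(sprintf("table '%s': ignoring unknown column(s): %s",
                    table, paste(extra, collapse = ", ")), call. = FALSE)
  out <- list()
  for (col in names(schema)) {
    v <- if (col %in% names(df)) df[[col]] else rep(NA, nrow(df))
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    out[[col]] <- switch(schema[[col]],
      integer = as.integer(v),
      numeric = as.numeric(v),
      date = if (inherits(v, "Date")) v else .parse_date(v),
      timestamp = .parse_ts(v),
      character = as.character(v))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Construct a patient store
#'
#' Assembles an in-memory OMOP-CDM-style population from its component
#' tables, coercing each to the documented column types (integer identifiers,
#' ISO-8601 timestamps at minute resolution in UTC, calendar dates).
#' Missing tables default to empty. Use [validate_store()] to check
#' referential and chronological integrity.
#'
#' @param person,drug_exposure,measurement,condition_occurrence,visit_occurrence,concept,concept_ancestor
#'   Data frames with the documented columns (see [read_patient_store()] for
#'   the file-level dialect); extra columns are dropped with a warning.
#' @return An object of class `patient_store`: a named list of the seven
#'   normalized tables.
#' @export
patient_store <- function(person = NULL, drug_exposure = NULL,
                          measurement = NULL, condition_occurrence = NULL,
                          visit_occurrence = NULL, concept = NULL,
                          concept_ancestor = NULL) {
  empty <- function(table) {
    schema <- .store_schemas[[table]]
    .coerce_table(as.data.frame(setNames(rep(list(character(0)), length(schema)),
                                         names(schema))), table)
  }
  tabs <- list(person = person, drug_exposure = drug_exposure,
               measurement = measurement,
               condition_occurrence = condition_occurrence,
               visit_occurrence = visit_occurrence, concept = concept,
               concept_ancestor = concept_ancestor)
  store <- lapply(names(tabs), function(nm) {
    if (is.null(tabs[[nm]]) || nrow(tabs[[nm]]) == 0L) empty(nm)
    else .coerce_table(tabs[[nm]], nm)
  })
  names(store) <- names(tabs)
  structure(store, class = "patient_store")
}

#' Empty patient store with the bundled vocabulary
#'
#' @return A `patient_store` with zero clinical rows whose `concept` and
#'   `concept_ancestor` tables hold the bundled synthetic vocabulary.
#' @export
empty_patient_store <- function() {
  v <- bundled_vocabulary()
  patient_store(concept = v$concept, concept_ancestor = v$concept_ancestor)
}

#' @export
print.patient_store <- function(x, ...) {
  cat("<patient_store>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %5d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Read a patient store from a directory of delimited tables
#'
#' Loads the comma-delimited, header-named tables `person.csv`,
#' `drug_exposure.csv`, `measurement.csv`, `condition_occurrence.csv`,
#' `visit_occurrence.csv`, `concept.csv` and `concept_ancestor.csv` (OMOP-CDM
#' v5 style column names, ISO-8601 timestamps). Date-only event times are
#' promoted to midnight UTC. Unknown extra columns are ignored with a
#' warning. The loaded store is integrity-checked; any violation (dangling
#' reference, reversed interval, impossible chronology) aborts the load with
#' a message listing the offending rows.
#'
#' @param directory_path Directory containing the seven table files.
#' @return A validated `patient_store`.
#' @seealso [write_patient_store()], [validate_store()]
#' @export
read_patient_store <- function(directory_path) {
  if (!dir.exists(directory_path))
    stop("store directory does not exist: ", directory_path)
  tabs <- lapply(names(.store_schemas), function(nm) {
    path <- file.path(directory_path, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path)
    .coerce_table(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"), nm)
  })
  names(tabs) <- names(.store_schemas)
  store <- structure(tabs, class = "patient_store")
  viol <- validate_store(store)
  if (nrow(viol) > 0L)
    stop("store failed integrity checks:\n",
         paste(utils::capture.output(print(viol)), collapse = "\n"))
  store
}

#' Write a patient store to a directory of delimited tables
#'
#' Inverse of [read_patient_store()]: writes the seven comma-delimited tables
#' with ISO-8601 timestamps so that reading them back reproduces the store
#' field-for-field.
#'
#' @param store A `patient_store`.
#' @param directory_path Output directory (created if absent).
#' @return `directory_path`, invisibly.
#' @export
write_patient_store <- function(store, directory_path) {
  stopifnot(inherits(store, "patient_store"))
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.store_schemas)) {
    df <- store[[nm]]
    schema <- .store_schemas[[nm]]
    out <- df
    for (col in names(schema)) {
      if (schema[[col]] == "timestamp") out[[col]] <- .format_ts(df[[col]])
      if (schema[[col]] == "date") out[[col]] <- ifelse(is.na(df[[col]]), "",
                                                        format(df[[col]], "%Y-%m-%d"))
    }
    write.csv(out, file.path(directory_path, paste0(nm, ".csv")),
              row.names = FALSE, na = "")
  }
  invisible(directory_path)
}

.violation <- function(entity, field, rule, rows) {
  data.frame(entity = entity, field = field, rule = rule,
             rows = paste(rows, collapse = ","), stringsAsFactors = FALSE)
}

#' Check the integrity of a patient store
#'
#' Applies every structural invariant of the data model and returns the
#' violations found rather than raising them: unique primary identifiers,
#' resolvable person references, ordered intervals (`start <= end`), event
#' dates not preceding the person's birth date, finite measurement values
#' with non-empty units, enumerated sex/route/visit-kind/vocabulary values,
#' and an acyclic concept ancestry.
#'
#' @param store A `patient_store`.
#' @return A data frame with columns `entity`, `field`, `rule`, `rows`
#'   (comma-separated offending row numbers); zero rows when the store is
#'   well formed.
#' @export
validate_store <- function(store) {
  v <- list()
  add <- function(entity, field, rule, bad) {
    if (any(bad, na.rm = TRUE))
      v[[length(v) + 1L]] <<- .violation(entity, field, rule, which(bad))
  }
  p <- store$person; dx <- store$drug_exposure; ms <- store$measurement
  co <- store$condition_occurrence; vo <- store$visit_occurrence
  cn <- store$concept; ca <- store$concept_ancestor

  add("person", "person_id", "unique identifier", duplicated(p$person_id))
  add("person", "person_id", "identifier present", is.na(p$person_id))
  add("person", "sex", "one of FEMALE/MALE", !is.na(p$sex) & !p$sex %in% .sex_levels)
  add("person", "birth_date", "birth date present", is.na(p$birth_date))
  add("concept", "concept_id", "unique identifier", duplicated(cn$concept_id))
  add("concept", "vocabulary", "one of RXNORM/LOINC/SNOMED",
      !cn$vocabulary %in% .vocab_levels)
  add("drug_exposure", "exposure_id", "unique identifier", duplicated(dx$exposure_id))
  add("drug_exposure", "person_id", "reference resolves",
      !dx$person_id %in% p$person_id)
  add("drug_exposure", "start_datetime", "start <= end",
      !is.na(dx$start_datetime) & !is.na(dx$end_datetime) &
        dx$start_datetime > dx$end_datetime)
  add("drug_exposure", "start_datetime", "timestamp present",
      is.na(dx$start_datetime) | is.na(dx$end_datetime))
  add("drug_exposure", "daily_dose_value", "finite and >= 0",
      !is.na(dx$daily_dose_value) &
        (!is.finite(dx$daily_dose_value) | dx$daily_dose_value < 0))
  add("drug_exposure", "route", "enumerated route",
      !is.na(dx$route) & !dx$route %in% .route_levels)
  add("measurement", "measurement_id", "unique identifier",
      duplicated(ms$measurement_id))
  add("measurement", "person_id", "reference resolves",
      !ms$person_id %in% p$person_id)
  add("measurement", "value", "finite value",
      is.na(ms$value) | !is.finite(ms$value))
  add("measurement", "unit", "unit non-empty when value present",
      !is.na(ms$value) & (is.na(ms$unit) | !nzchar(ms$unit)))
  add("condition_occurrence", "person_id", "reference resolves",
      !co$person_id %in% p$person_id)
  add("condition_occurrence", "end_date", "end >= start",
      !is.na(co$end_date) & !is.na(co$start_date) & co$end_date < co$start_date)
  add("visit_occurrence", "visit_id", "unique identifier", duplicated(vo$visit_id))
  add("visit_occurrence", "person_id", "reference resolves",
      !vo$person_id %in% p$person_id)
  add("visit_occurrence", "start_datetime", "start <= end",
      !is.na(vo$start_datetime) & !is.na(vo$end_datetime) &
        vo$start_datetime > vo$end_datetime)
  add("visit_occurrence", "visit_kind", "enumerated visit kind",
      !is.na(vo$visit_kind) & !vo$visit_kind %in% .visit_kind_levels)

  # concept references from events
  known <- cn$concept_id
  add("drug_exposure", "drug_concept_id", "reference resolves",
      !dx$drug_concept_id %in% known)
  add("measurement", "measurement_concept_id", "reference resolves",
      !ms$measurement_concept_id %in% known)
  add("condition_occurrence", "condition_concept_id", "reference resolves",
      !co$condition_concept_id %in% known)
  add("concept_ancestor", "ancestor_concept_id", "reference resolves",
      !ca$ancestor_concept_id %in% known)
  add("concept_ancestor", "descendant_concept_id", "reference resolves",
      !ca$descendant_concept_id %in% known)

  # birth date precedes or equals every event time of that person
  birth <- setNames(p$birth_date, p$person_id)
  ev_bad <- function(pid, t) {
    b <- birth[as.character(pid)]
    !is.na(t) & !is.na(b) & as.Date(t, tz = "UTC") < b
  }
  add("person", "birth_date", "birth precedes drug exposure",
      ev_bad(dx$person_id, dx$start_datetime))
  add("person", "birth_date", "birth precedes measurement",
      ev_bad(ms$person_id, ms$taken_datetime))
  add("person", "birth_date", "birth precedes condition",
      !is.na(co$start_date) & !is.na(birth[as.character(co$person_id)]) &
        co$start_date < birth[as.character(co$person_id)])
  add("person", "birth_date", "birth precedes visit",
      ev_bad(vo$person_id, vo$start_datetime))

  # ancestry acyclicity: iterative leaf stripping (Kahn)
  if (nrow(ca) > 0L) {
    edges <- unique(ca[, c("ancestor_concept_id", "descendant_concept_id")])
    repeat {
      sinks <- setdiff(edges$descendant_concept_id, edges$ancestor_concept_id)
      keep <- !edges$descendant_concept_id %in% sinks
      if (all(keep)) break
      edges <- edges[keep, , drop = FALSE]
    }
    if (nrow(edges) > 0L)
      v[[length(v) + 1L]] <- .violation("concept_ancestor", "ancestry",
                                        "acyclic", seq_len(nrow(edges)))
  }

  if (length(v) == 0L)
    return(data.frame(entity = character(0), field = character(0),
                      rule = character(0), rows = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Restrict a store to visits of a minimum duration
#'
#' Keeps only visits lasting at least `min_hours` (duration computed as end
#' minus start in hours; the lower bound is inclusive, so a visit of exactly
#' 24 hours survives a 24-hour threshold). Optionally also drops clinical
#' events that do not fall inside any retained visit of the same person;
#' by default events outside visits are retained.
#'
#' @param store A `patient_store`.
#' @param min_hours Non-negative visit duration threshold in hours.
#' @param events_within_visits If `TRUE`, drug exposures, measurements and
#'   condition occurrences are kept only when their start time lies within a
#'   retained visit of the same person. Default `FALSE` (retain all events).
#' @return A new `patient_store`; the input is not modified.
#' @export
filter_visits_min_duration <- function(store, min_hours,
                                       events_within_visits = FALSE) {
  stopifnot(inherits(store, "patient_store"))
  if (!is.numeric(min_hours) || length(min_hours) != 1L || is.na(min_hours) ||
      min_hours < 0)
    stop("min_hours must be a single non-negative number")
  vo <- store$visit_occurrence
  dur <- as.numeric(difftime(vo$end_datetime, vo$start_datetime, units = "hours"))
  keep <- !is.na(dur) & dur >= min_hours
  out <- unclass(store)
  out$visit_occurrence <- vo[keep, , drop = FALSE]
  rownames(out$visit_occurrence) <- NULL
  if (events_within_visits) {
    vis <- out$visit_occurrence
    inside <- function(pid, t) {
      vapply(seq_along(pid), function(i) {
        if (is.na(t[i])) return(FALSE)
        any(vis$person_id == pid[i] & vis$start_datetime <= t[i] &
              vis$end_datetime >= t[i])
      }, logical(1))
    }
    dx <- out$drug_exposure
    out$drug_exposure <- dx[inside(dx$person_id, dx$start_datetime), , drop = FALSE]
    ms <- out$measurement
    out$measurement <- ms[inside(ms$person_id, ms$taken_datetime), , drop = FALSE]
    co <- out$condition_occurrence
    out$condition_occurrence <-
      co[inside(co$person_id, .parse_ts(format(co$start_date))), , drop = FALSE]
    for (nm in c("drug_exposure", "measurement", "condition_occurrence"))
      rownames(out[[nm]]) <- NULL
  }
  structure(out, class = "patient_store")
}
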
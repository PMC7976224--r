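#' Do two drug exposures overlap in time?
#'
#' Exposure periods are closed intervals; endpoints are inclusive, so two
#' exposures that share a single timestamp overlap. This is the
#' alert-retaining reading of "the start and stop dates of the two drugs
#' overlapped": a conventional interaction alert would fire at the shared
#' boundary moment.
#'
#' @param start1,end1,start2,end2 POSIXct timestamps of the two exposure
#'   periods (vectorized).
#' @return Logical vector; symmetric in the two exposures.
#' @export
exposures_overlap <- function(start1, end1, start2, end2) {
  start1 <= end2 & start2 <= end1
}

#' Find basic concomitant exposures between two drug sets
#'
#' The trigger condition for a conventional DDI alert: one exposure to a
#' drug in the object set and one to a drug in the precipitant set, for the
#' same person, with overlapping (endpoint-inclusive) periods. Every unique
#' ordered (object exposure, precipitant exposure) combination is one pair;
#' exposures that share an identical start timestamp but differ in
#' free-text dose direction are distinct rows and therefore yield distinct
#' pairs. A self-pair (the same exposure row on both sides, possible when
#' the two sets intersect) is excluded. The trigger time is the start of
#' the later-starting exposure — the order-entry moment at which an alert
#' would fire; when the starts tie, the shared start.
#'
#' @param store A `patient_store`.
#' @param set_a Resolved object-drug concept set.
#' @param set_b Resolved precipitant-drug concept set.
#' @return Data frame with columns `person_id`, `object_exposure_id`,
#'   `precipitant_exposure_id`, `trigger_datetime`, `overlap_start`,
#'   `overlap_end`, sorted by person, trigger time and exposure ids.
#' @export
find_concomitant_pairs <- function(store, set_a, set_b) {
  dx <- store$drug_exposure
  a <- dx[is_member(dx$drug_concept_id, set_a), , drop = FALSE]
  b <- dx[is_member(dx$drug_concept_id, set_b), , drop = FALSE]
  empty <- data.frame(person_id = integer(0), object_exposure_id = integer(0),
                      precipitant_exposure_id = integer(0),
                      trigger_datetime = .parse_ts(character(0)),
                      overlap_start = .parse_ts(character(0)),
                      overlap_end = .parse_ts(character(0)))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  m <- merge(
    a[, c("person_id", "exposure_id", "start_datetime", "end_datetime")],
    b[, c("person_id", "exposure_id", "start_datetime", "end_datetime")],
    by = "person_id", suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) return(empty)
  keep <- m$exposure_id_a != m$exposure_id_b &
    exposures_overlap(m$start_datetime_a, m$end_datetime_a,
                      m$start_datetime_b, m$end_datetime_b)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  out <- data.frame(
    person_id = m$person_id,
    object_exposure_id = m$exposure_id_a,
    precipitant_exposure_id = m$exposure_id_b,
    trigger_datetime = pmax(m$start_datetime_a, m$start_datetime_b),
    overlap_start = pmax(m$start_datetime_a, m$start_datetime_b),
    overlap_end = pmin(m$end_datetime_a, m$end_datetime_b))
  out <- out[order(out$person_id, out$trigger_datetime,
                   out$object_exposure_id, out$precipitant_exposure_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# potassium is reported interchangeably in mEq/L and mmol/L (1:1 for a
# monovalent ion); normalize spelling so threshold comparisons are unit-safe
.normalize_unit <- function(unit) {
  u <- tolower(trimws(unit %||% ""))
  if (u %in% c("mmol/l", "meq/l", "meq", "mmol")) return("mEq/L")
  unit
}

#' Most recent laboratory value before a time point
#'
#' Returns the value of the measurement whose concept lies in `lab_set`
#' with the greatest `taken_datetime` at or before `as_of` and within the
#' lookback window. Measurements after `as_of` are never considered (no
#' future peeking). Ties on the timestamp are broken by the larger
#' measurement id (the later-recorded row).
#'
#' @param store A `patient_store`.
#' @param person_id Person identifier.
#' @param lab_set Resolved concept set of laboratory concepts.
#' @param as_of POSIXct evaluation time.
#' @param lookback_days Positive window length in days.
#' @return A list with `value`, `unit` and `measurement_id`, or `NULL` when
#'   no qualifying measurement exists (the MISSING outcome).
#' @export
latest_measurement <- function(store, person_id, lab_set, as_of, lookback_days) {
  if (!is.numeric(lookback_days) || lookback_days <= 0)
    stop("lookback_days must be positive")
  ms <- store$measurement
  lo <- as_of - lookback_days * 86400
  cand <- ms[ms$person_id == person_id &
               is_member(ms$measurement_concept_id, lab_set) &
               !is.na(ms$taken_datetime) &
               ms$taken_datetime <= as_of & ms$taken_datetime >= lo, ,
             drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(cand$taken_datetime, cand$measurement_id), , drop = FALSE]
  last <- cand[nrow(cand), ]
  list(value = last$value, unit = .normalize_unit(last$unit),
       measurement_id = last$measurement_id)
}

#' Age in completed years at a time point
#'
#' Birthday-anniversary convention: the person turns `n` on the `n`-th
#' anniversary of the birth date, so an "age 68 or older" criterion is
#' satisfied on the 68th birthday itself.
#'
#' @param birth_date `Date` of birth.
#' @param as_of POSIXct or Date evaluation time, not before birth.
#' @return Integer completed years.
#' @export
age_at <- function(birth_date, as_of) {
  d <- as.Date(as_of, tz = "UTC")
  if (any(d < birth_date)) stop("as_of precedes birth_date")
  b <- as.POSIXlt(birth_date); a <- as.POSIXlt(d)
  yrs <- a$year - b$year
  before_anniv <- a$mon < b$mon | (a$mon == b$mon & a$mday < b$mday)
  as.integer(yrs - before_anniv)
}

#' Does a person carry a condition at a time point?
#'
#' Two readings matching the phrasing used by condition factors:
#' `"EVER"` ("history of ...") is any occurrence starting at or before
#' `as_of`; `"ACTIVE"` ("has diagnosis of ...") requires the occurrence
#' interval (open-ended when no end date is recorded) to contain `as_of`.
#'
#' @param store A `patient_store`.
#' @param person_id Person identifier.
#' @param cond_set Resolved concept set of condition concepts.
#' @param as_of POSIXct evaluation time.
#' @param mode `"EVER"` or `"ACTIVE"`.
#' @return Single logical.
#' @export
has_active_condition <- function(store, person_id, cond_set, as_of,
                                 mode = c("EVER", "ACTIVE")) {
  mode <- match.arg(mode)
  co <- store$condition_occurrence
  d <- as.Date(as_of, tz = "UTC")
  rows <- co[co$person_id == person_id &
               is_member(co$condition_concept_id, cond_set) &
               !is.na(co$start_date) & co$start_date <= d, , drop = FALSE]
  if (nrow(rows) == 0L) return(FALSE)
  if (mode == "EVER") return(TRUE)
  any(is.na(rows$end_date) | rows$end_date >= d)
}

#' Detect a recent discontinuation of a drug
#'
#' `TRUE` when some exposure in `drug_set` ended within the window
#' `[as_of - window_days, as_of]` and no exposure in the set is ongoing at
#' `as_of` — i.e. the drug was stopped recently and not restarted. Used for
#' withdrawal factors such as abrupt clonidine discontinuation under
#' continued beta-blockade.
#'
#' @param store A `patient_store`.
#' @param person_id Person identifier.
#' @param drug_set Resolved drug concept set.
#' @param as_of POSIXct evaluation time.
#' @param window_days Positive window length in days.
#' @return Single logical.
#' @export
detect_discontinuation <- function(store, person_id, drug_set, as_of,
                                   window_days) {
  if (!is.numeric(window_days) || window_days <= 0)
    stop("window_days must be positive")
  dx <- store$drug_exposure
  rows <- dx[dx$person_id == person_id &
               is_member(dx$drug_concept_id, drug_set), , drop = FALSE]
  if (nrow(rows) == 0L) return(FALSE)
  ongoing <- any(rows$start_datetime <= as_of & rows$end_datetime >= as_of)
  if (ongoing) return(FALSE)
  lo <- as_of - window_days * 86400
  any(rows$end_datetime >= lo & rows$end_datetime <= as_of)
}

#' Context-extraction configuration
#'
#' Bundles the tunable windows used when extracting patient-context factors:
#' how far back a laboratory value may be trusted, and how wide the
#' drug-withdrawal window is. Defaults: serum potassium 3 days (an
#' inpatient-style recency requirement), QTc 30 days (ECGs are repeated far
#' less often), withdrawal window 7 days. All are plain numbers of days and
#' can be overridden per call or loaded from a JSON document.
#'
#' @param lookback_days Named numeric vector of per-lab-set lookback windows
#'   in days (names are concept-set ids).
#' @param default_lookback_days Lookback for lab sets not named above.
#' @param withdrawal_window_days Window for discontinuation factors.
#' @return An object of class `context_config`.
#' @export
context_config <- function(lookback_days = c(serum_potassium_lab = 3,
                                             qtc_lab = 30),
                           default_lookback_days = 30,
                           withdrawal_window_days = 7) {
  structure(list(lookback_days = lookback_days,
                 default_lookback_days = default_lookback_days,
                 withdrawal_window_days = withdrawal_window_days),
            class = "context_config")
}

#' Read a context configuration document
#'
#' @param path JSON document with fields `lookback_days` (object mapping
#'   lab-set id to days), `default_lookback_days` and
#'   `withdrawal_window_days`; defaults to the bundled configuration.
#' @return A `context_config`.
#' @export
read_context_config <- function(path = system.file("config",
                                                   "context_config.json",
                                                   package = "ddialert")) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  context_config(lookback_days = unlist(doc$lookback_days),
                 default_lookback_days = doc$default_lookback_days %||% 30,
                 withdrawal_window_days = doc$withdrawal_window_days %||% 7)
}

.lookback_for <- function(config, set_id, override = NULL) {
  if (!is.null(override)) return(override)
  lb <- config$lookback_days
  if (!is.null(names(lb)) && set_id %in% names(lb)) return(unname(lb[[set_id]]))
  config$default_lookback_days
}
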
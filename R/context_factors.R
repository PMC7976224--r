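# Patient-context factor extraction.
#
# Each decision tree declares a factor manifest: (name, type, extractor,
# params). Extractors pull one typed value out of the store at the trigger
# time of a concomitant pair. MISSING is represented as NA; boolean factors
# derived from record absence (conditions, concomitant drugs) are FALSE
# rather than MISSING, because an empty record is evidence of absence in
# this data model, while labs, doses and routes can genuinely be unrecorded.

.exposure_row <- function(store, exposure_id) {
  dx <- store$drug_exposure
  dx[match(exposure_id, dx$exposure_id), , drop = FALSE]
}

.pair_exposure <- function(store, pair, which) {
  id <- if (identical(which, "precipitant")) pair$precipitant_exposure_id
        else pair$object_exposure_id
  .exposure_row(store, id)
}

.need_set <- function(sets, set_id, where) {
  if (is.null(sets[[set_id]]))
    stop("factor '", where, "' references unresolved concept set '", set_id, "'")
  sets[[set_id]]
}

# extractor registry: each returns list(value = <typed or NA>, prov = <id or NA>)
.extractors <- list(
  sex_female = function(store, pair, tree, config, sets, params) {
    p <- store$person[match(pair$person_id, store$person$person_id), ]
    list(value = identical(p$sex, "FEMALE"), prov = pair$person_id)
  },
  age = function(store, pair, tree, config, sets, params) {
    p <- store$person[match(pair$person_id, store$person$person_id), ]
    list(value = age_at(p$birth_date, pair$trigger_datetime),
         prov = pair$person_id)
  },
  age_flag = function(store, pair, tree, config, sets, params) {
    p <- store$person[match(pair$person_id, store$person$person_id), ]
    list(value = age_at(p$birth_date, pair$trigger_datetime) >= params$threshold,
         prov = pair$person_id)
  },
  latest_lab = function(store, pair, tree, config, sets, params) {
    lab <- latest_measurement(
      store, pair$person_id, .need_set(sets, params$set, "latest_lab"),
      pair$trigger_datetime,
      .lookback_for(config, params$set, params$lookback_days))
    if (is.null(lab)) list(value = NA_real_, prov = NA_integer_)
    else list(value = lab$value, prov = lab$measurement_id)
  },
  lab_flag = function(store, pair, tree, config, sets, params) {
    lab <- latest_measurement(
      store, pair$person_id, .need_set(sets, params$set, "lab_flag"),
      pair$trigger_datetime,
      .lookback_for(config, params$set, params$lookback_days))
    if (is.null(lab)) return(list(value = NA, prov = NA_integer_))
    v <- switch(params$comparator,
                LT = lab$value < params$threshold,
                LE = lab$value <= params$threshold,
                GT = lab$value > params$threshold,
                GE = lab$value >= params$threshold,
                stop("lab_flag: unsupported comparator ", params$comparator))
    list(value = v, prov = lab$measurement_id)
  },
  condition = function(store, pair, tree, config, sets, params) {
    list(value = has_active_condition(
      store, pair$person_id, .need_set(sets, params$set, "condition"),
      pair$trigger_datetime, mode = params$mode %||% "EVER"),
      prov = NA_integer_)
  },
  concomitant_drug = function(store, pair, tree, config, sets, params) {
    set <- .need_set(sets, params$set, "concomitant_drug")
    dx <- store$drug_exposure
    own <- c(pair$object_exposure_id, pair$precipitant_exposure_id)
    hit <- dx$person_id == pair$person_id &
      !dx$exposure_id %in% own &
      is_member(dx$drug_concept_id, set) &
      dx$start_datetime <= pair$trigger_datetime &
      dx$end_datetime >= pair$trigger_datetime
    list(value = any(hit),
         prov = if (any(hit)) dx$exposure_id[which(hit)[1L]] else NA_integer_)
  },
  drug_class = function(store, pair, tree, config, sets, params) {
    ex <- .pair_exposure(store, pair, params$which %||% "precipitant")
    for (cl in params$classes) {
      if (is_member(ex$drug_concept_id, .need_set(sets, cl$set, "drug_class")))
        return(list(value = cl$label, prov = ex$exposure_id))
    }
    list(value = "OTHER", prov = ex$exposure_id)
  },
  drug_route = function(store, pair, tree, config, sets, params) {
    ex <- .pair_exposure(store, pair, params$which %||% "object")
    list(value = ex$route, prov = ex$exposure_id)
  },
  drug_route_in = function(store, pair, tree, config, sets, params) {
    ex <- .pair_exposure(store, pair, params$which %||% "precipitant")
    set <- .need_set(sets, params$set, "drug_route_in")
    v <- is_member(ex$drug_concept_id, set) &&
      !is.na(ex$route) && ex$route %in% params$routes
    list(value = v, prov = ex$exposure_id)
  },
  daily_dose = function(store, pair, tree, config, sets, params) {
    ex <- .pair_exposure(store, pair, params$which %||% "object")
    list(value = ex$daily_dose_value, prov = ex$exposure_id)
  },
  withdrawal = function(store, pair, tree, config, sets, params) {
    # withdrawal of the object drug while the precipitant continues: the
    # object exposure ends strictly before the precipitant exposure does,
    # and no other object-set exposure is ongoing one minute after that end
    obj <- .pair_exposure(store, pair, "object")
    prec <- .pair_exposure(store, pair, "precipitant")
    if (obj$end_datetime >= prec$end_datetime)
      return(list(value = FALSE, prov = obj$exposure_id))
    probe <- obj$end_datetime + 60
    set <- .need_set(sets, params$set %||% tree$object_set, "withdrawal")
    dx <- store$drug_exposure
    ongoing <- dx$person_id == pair$person_id &
      dx$exposure_id != obj$exposure_id &
      is_member(dx$drug_concept_id, set) &
      dx$start_datetime <= probe & dx$end_datetime >= probe
    list(value = !any(ongoing), prov = obj$exposure_id)
  },
  inpatient = function(store, pair, tree, config, sets, params) {
    vo <- store$visit_occurrence
    min_hours <- params$min_hours %||% 24
    cover <- vo$person_id == pair$person_id &
      !is.na(vo$start_datetime) & !is.na(vo$end_datetime) &
      vo$start_datetime <= pair$trigger_datetime &
      vo$end_datetime >= pair$trigger_datetime
    if (!any(cover)) return(list(value = FALSE, prov = NA_integer_))
    vv <- vo[cover, , drop = FALSE]
    dur <- as.numeric(difftime(vv$end_datetime, vv$start_datetime,
                               units = "hours"))
    hit <- (!is.na(vv$visit_kind) & vv$visit_kind == "INPATIENT") |
      dur >= min_hours
    list(value = any(hit),
         prov = if (any(hit)) vv$visit_id[which(hit)[1L]] else vv$visit_id[1L])
  },
  risk_count = NULL  # derived; handled by .finalize_factors
)

# derived factors: risk_count sums its boolean components, counting a
# MISSING component as present (the alert-retaining reading of missing data)
.finalize_factors <- function(tree, values) {
  for (f in tree$factors) {
    if (!identical(f$extractor, "risk_count")) next
    comp <- unlist(f$params$components)
    vals <- values[comp]
    values[[f$name]] <- sum(vapply(vals, function(v)
      is.na(v) || isTRUE(v), logical(1)))
  }
  values
}

#' Complete a set of primitive factor values for a tree
#'
#' Fills in the tree's derived factors (risk-factor counts) from primitive
#' factor values and returns the complete factor map in manifest order.
#' This is the same finalization step [build_context()] applies after
#' record-level extraction, exposed so that decision trees can be evaluated
#' on constructed contexts (e.g. exhaustive factor lattices in tests)
#' without a backing store.
#'
#' @param tree A `ddi_tree`.
#' @param values Named list of primitive factor values (`NA` = MISSING).
#'   Primitive factors left unnamed default to `NA`.
#' @return Named list covering every factor in the tree's manifest.
#' @export
evaluate_factors <- function(tree, values) {
  prim <- setdiff(vapply(tree$factors, `[[`, "", "name"),
                  names(values))
  derived <- vapply(tree$factors, function(f)
    identical(f$extractor, "risk_count"), logical(1))
  derived_names <- vapply(tree$factors, `[[`, "", "name")[derived]
  for (nm in setdiff(prim, derived_names)) values[[nm]] <- NA
  values <- .finalize_factors(tree, values)
  all_names <- vapply(tree$factors, `[[`, "", "name")
  values[all_names]
}

#' Extract the patient context for one concomitant pair
#'
#' Populates every factor declared by the tree's manifest — no more, no
#' fewer — at `as_of = trigger_datetime` of the pair, recording for each
#' factor the identifier of the source event (measurement, exposure, visit
#' or person record) where one exists. Unextractable values are MISSING
#' (`NA`); an extractor name the package does not support is a
#' configuration error.
#'
#' @param store A `patient_store`.
#' @param pair One-row data frame from [find_concomitant_pairs()].
#' @param tree A `ddi_tree`.
#' @param config A `context_config`.
#' @param sets Named list of resolved concept sets (from
#'   [resolve_concept_sets()]).
#' @return An object of class `patient_context`: list with `person_id`,
#'   `as_of`, `age_years`, `sex`, `factor_values`, `provenance`.
#' @export
build_context <- function(store, pair, tree, config = context_config(),
                          sets) {
  stopifnot(nrow(pair) == 1L)
  values <- list(); prov <- list()
  for (f in tree$factors) {
    if (identical(f$extractor, "risk_count")) next
    fn <- .extractors[[f$extractor]]
    if (is.null(fn))
      stop("factor '", f$name, "': no extractor named '", f$extractor, "'")
    res <- fn(store, pair, tree, config, sets, f$params %||% list())
    values[[f$name]] <- res$value
    prov[[f$name]] <- res$prov
  }
  values <- .finalize_factors(tree, values)
  p <- store$person[match(pair$person_id, store$person$person_id), ]
  structure(list(person_id = pair$person_id,
                 as_of = pair$trigger_datetime,
                 age_years = age_at(p$birth_date, pair$trigger_datetime),
                 sex = p$sex,
                 factor_values = values,
                 provenance = prov),
            class = "patient_context")
}

#' @export
print.patient_context <- function(x, ...) {
  cat(sprintf("<patient_context> person %d at %s (age %d, %s)\n",
              x$person_id, .format_ts(x$as_of), x$age_years, x$sex))
  for (nm in names(x$factor_values)) {
    v <- x$factor_values[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (length(v) == 0 || all(is.na(v))) "MISSING" else format(v)))
  }
  invisible(x)
}
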
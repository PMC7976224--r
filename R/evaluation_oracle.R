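# Independent re-computation of alert counts, mirroring the validation
# practice of checking a rule engine against separately written relational
# queries. Everything here is deliberately re-derived from the raw store
# tables with plain nested scans: no function from the exposure-logic or
# rule-evaluation modules is called (a test enforces that import boundary),
# so agreement between engine and oracle is evidence about the semantics,
# not an artifact of shared code.

#' Daily alert counts by exhaustive scan
#'
#' Recomputes, for one DDI tree, the number of basic concomitant exposures
#' and their Red/Yellow/Green classification per calendar day (UTC date of
#' the trigger time), using an independent brute-force code path over the
#' raw tables.
#'
#' @param store A `patient_store`.
#' @param tree A `ddi_tree`.
#' @param config A `context_config`.
#' @param definitions Concept-set definitions (defaults to the bundled
#'   documents); membership is recomputed here with a standalone closure.
#' @return Data frame `ddi_id`, `date`, `n_basic`, `n_red`, `n_yellow`,
#'   `n_green`.
#' @export
oracle_daily_counts <- function(store, tree, config = context_config(),
                                definitions = bundled_concept_sets()) {
  anc <- store$concept_ancestor

  members_of <- function(set_id) {
    def <- definitions[[set_id]]
    if (is.null(def)) stop("oracle: unknown concept set '", set_id, "'")
    mem <- def$seed_concept_ids
    if (def$include_descendants) {
      frontier <- mem
      repeat {
        kids <- anc$descendant_concept_id[anc$ancestor_concept_id %in% frontier]
        kids <- setdiff(unique(kids), mem)
        if (length(kids) == 0L) break
        mem <- c(mem, kids)
        frontier <- kids
      }
    }
    setdiff(mem, def$excluded_concept_ids)
  }

  dx <- store$drug_exposure
  obj_members <- members_of(tree$object_set)
  prec_members <- members_of(tree$precipitant_set)
  lookback <- function(set_id) {
    lb <- config$lookback_days
    if (!is.null(names(lb)) && set_id %in% names(lb)) unname(lb[[set_id]])
    else config$default_lookback_days
  }

  completed_years <- function(birth, at_date) {
    by <- as.integer(format(birth, "%Y")); ay <- as.integer(format(at_date, "%Y"))
    bm <- format(birth, "%m%d"); am <- format(at_date, "%m%d")
    ay - by - (am < bm)
  }

  extract <- function(person_row, t, obj_row, prec_row) {
    t_date <- as.Date(t, tz = "UTC")
    side_row <- function(which)
      if (identical(which, "precipitant")) prec_row else obj_row
    vals <- list()
    for (f in tree$factors) {
      p <- f$params
      vals[[f$name]] <- switch(f$extractor,
        sex_female = identical(person_row$sex, "FEMALE"),
        age = completed_years(person_row$birth_date, t_date),
        age_flag = completed_years(person_row$birth_date, t_date) >=
          p$threshold,
        latest_lab = , lab_flag = {
          mem <- members_of(p$set)
          lb <- if (!is.null(p$lookback_days)) p$lookback_days
                else lookback(p$set)
          ms <- store$measurement
          best <- NULL
          for (r in seq_len(nrow(ms))) {
            if (ms$person_id[r] != person_row$person_id) next
            if (!ms$measurement_concept_id[r] %in% mem) next
            tt <- ms$taken_datetime[r]
            if (is.na(tt) || tt > t || tt < t - lb * 86400) next
            if (is.null(best) || tt > ms$taken_datetime[best] ||
                (tt == ms$taken_datetime[best] &&
                 ms$measurement_id[r] > ms$measurement_id[best]))
              best <- r
          }
          if (is.null(best)) {
            if (f$extractor == "latest_lab") NA_real_ else NA
          } else if (f$extractor == "latest_lab") {
            ms$value[best]
          } else {
            switch(p$comparator,
                   LT = ms$value[best] < p$threshold,
                   LE = ms$value[best] <= p$threshold,
                   GT = ms$value[best] > p$threshold,
                   GE = ms$value[best] >= p$threshold)
          }
        },
        condition = {
          mem <- members_of(p$set)
          co <- store$condition_occurrence
          hit <- FALSE
          for (r in seq_len(nrow(co))) {
            if (co$person_id[r] != person_row$person_id) next
            if (!co$condition_concept_id[r] %in% mem) next
            if (is.na(co$start_date[r]) || co$start_date[r] > t_date) next
            if (identical(p$mode, "ACTIVE") &&
                !is.na(co$end_date[r]) && co$end_date[r] < t_date) next
            hit <- TRUE; break
          }
          hit
        },
        concomitant_drug = {
          mem <- members_of(p$set)
          hit <- FALSE
          for (r in seq_len(nrow(dx))) {
            if (dx$person_id[r] != person_row$person_id) next
            if (dx$exposure_id[r] %in% c(obj_row$exposure_id,
                                         prec_row$exposure_id)) next
            if (!dx$drug_concept_id[r] %in% mem) next
            if (dx$start_datetime[r] <= t && dx$end_datetime[r] >= t) {
              hit <- TRUE; break
            }
          }
          hit
        },
        drug_class = {
          ex <- side_row(p$which %||% "precipitant")
          lbl <- "OTHER"
          for (cl in p$classes)
            if (ex$drug_concept_id %in% members_of(cl$set)) {
              lbl <- cl$label; break
            }
          lbl
        },
        drug_route = side_row(p$which %||% "object")$route,
        drug_route_in = {
          ex <- side_row(p$which %||% "precipitant")
          ex$drug_concept_id %in% members_of(p$set) &&
            !is.na(ex$route) && ex$route %in% unlist(p$routes)
        },
        daily_dose = side_row(p$which %||% "object")$daily_dose_value,
        withdrawal = {
          if (obj_row$end_datetime >= prec_row$end_datetime) FALSE
          else {
            probe <- obj_row$end_datetime + 60
            mem <- members_of(p$set %||% tree$object_set)
            ongoing <- FALSE
            for (r in seq_len(nrow(dx))) {
              if (dx$person_id[r] != person_row$person_id) next
              if (dx$exposure_id[r] == obj_row$exposure_id) next
              if (!dx$drug_concept_id[r] %in% mem) next
              if (dx$start_datetime[r] <= probe &&
                  dx$end_datetime[r] >= probe) { ongoing <- TRUE; break }
            }
            !ongoing
          }
        },
        inpatient = {
          vo <- store$visit_occurrence
          min_hours <- p$min_hours %||% 24
          hit <- FALSE
          for (r in seq_len(nrow(vo))) {
            if (vo$person_id[r] != person_row$person_id) next
            if (is.na(vo$start_datetime[r]) || is.na(vo$end_datetime[r])) next
            if (vo$start_datetime[r] > t || vo$end_datetime[r] < t) next
            dur <- as.numeric(difftime(vo$end_datetime[r],
                                       vo$start_datetime[r], units = "hours"))
            if ((!is.na(vo$visit_kind[r]) &&
                 vo$visit_kind[r] == "INPATIENT") || dur >= min_hours) {
              hit <- TRUE; break
            }
          }
          hit
        },
        risk_count = NA,  # filled below
        stop("oracle: unsupported extractor '", f$extractor, "'"))
    }
    for (f in tree$factors) {
      if (!identical(f$extractor, "risk_count")) next
      comp <- unlist(f$params$components)
      total <- 0L
      for (nm in comp) {
        v <- vals[[nm]]
        if (is.na(v) || isTRUE(v)) total <- total + 1L
      }
      vals[[f$name]] <- total
    }
    vals
  }

  classify <- function(vals) {
    walk <- function(id) {
      n <- tree$nodes[[id]]
      if (identical(n$kind, "leaf")) return(n$color)
      v <- vals[[n$factor]]
      missing <- length(v) == 0L || all(is.na(v))
      taken <- if (n$comparator == "PRESENT") !missing
        else if (n$comparator == "ABSENT") missing
        else if (missing) identical(n$missing_branch, "TRUE_BRANCH")
        else switch(n$comparator,
                    LT = v < n$threshold, LE = v <= n$threshold,
                    GT = v > n$threshold, GE = v >= n$threshold,
                    EQ = if (is.logical(v)) v == isTRUE(as.logical(n$threshold))
                         else v == n$threshold,
                    IN_SET = v %in% unlist(n$threshold))
      walk(if (isTRUE(taken)) n$true_branch else n$false_branch)
    }
    walk(tree$root)
  }

  dates <- character(0); colors <- character(0)
  persons <- store$person
  for (i in seq_len(nrow(dx))) {
    if (!dx$drug_concept_id[i] %in% obj_members) next
    for (j in seq_len(nrow(dx))) {
      if (i == j) next
      if (dx$person_id[j] != dx$person_id[i]) next
      if (!dx$drug_concept_id[j] %in% prec_members) next
      if (dx$start_datetime[i] > dx$end_datetime[j] ||
          dx$start_datetime[j] > dx$end_datetime[i]) next
      trig <- if (dx$start_datetime[i] >= dx$start_datetime[j])
        dx$start_datetime[i] else dx$start_datetime[j]
      prow <- persons[persons$person_id == dx$person_id[i], , drop = FALSE]
      vals <- extract(prow[1L, ], trig, dx[i, ], dx[j, ])
      dates <- c(dates, format(as.Date(trig, tz = "UTC")))
      colors <- c(colors, classify(vals))
    }
  }
  .daily_count_frame(rep(tree$ddi_id, length(dates)), as.Date(dates),
                     colors, tree$ddi_id)
}

#' Compare engine and oracle daily counts
#'
#' Enumerates, per DDI and calendar date, every disagreement between the
#' engine's counts and the oracle's (basic and per-color). The two inputs
#' must cover the same DDI identifiers.
#'
#' @param engine Data frame from [engine_daily_counts()].
#' @param oracle Data frame from [oracle_daily_counts()] (or several
#'   row-bound together).
#' @return An object of class `ddi_concordance`: list with `concordant`
#'   (logical) and `discrepancies` (data frame `ddi_id`, `date`, `metric`,
#'   `engine`, `oracle`).
#' @export
compare_daily_counts <- function(engine, oracle) {
  if (!setequal(unique(engine$ddi_id), unique(oracle$ddi_id)))
    stop("engine and oracle cover different ddi_id sets")
  metrics <- c("n_basic", "n_red", "n_yellow", "n_green")
  key <- function(d) paste(d$ddi_id, d$date)
  all_keys <- union(key(engine), key(oracle))
  disc <- list()
  for (k in all_keys) {
    e <- engine[key(engine) == k, , drop = FALSE]
    o <- oracle[key(oracle) == k, , drop = FALSE]
    for (m in metrics) {
      ev <- if (nrow(e)) e[[m]][1L] else 0L
      ov <- if (nrow(o)) o[[m]][1L] else 0L
      if (ev != ov) {
        parts <- strsplit(k, " ")[[1L]]
        disc[[length(disc) + 1L]] <- data.frame(
          ddi_id = parts[1L], date = parts[2L], metric = m,
          engine = ev, oracle = ov, stringsAsFactors = FALSE)
      }
    }
  }
  disc <- if (length(disc)) do.call(rbind, disc) else
    data.frame(ddi_id = character(0), date = character(0),
               metric = character(0), engine = integer(0),
               oracle = integer(0), stringsAsFactors = FALSE)
  structure(list(concordant = nrow(disc) == 0L, discrepancies = disc),
            class = "ddi_concordance")
}

#' @export
print.ddi_concordance <- function(x, ...) {
  if (x$concordant) cat("<ddi_concordance> concordant: no discrepancies\n")
  else {
    cat("<ddi_concordance> DISCORDANT:", nrow(x$discrepancies),
        "discrepancies\n")
    print(x$discrepancies)
  }
  invisible(x)
}
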
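# Shared fixture builders. Everything is constructed in code; the bundled
# synthetic vocabulary backs all concept references.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Build a small store from compact row lists. Each element of `exposures`
# is list(person, drug, start, end, dose=, unit=, route=, dir=);
# `measurements`: list(person, concept, taken, value, unit);
# `conditions`: list(person, concept, start, end=NA);
# `visits`: list(person, start, end, kind="UNKNOWN");
# `persons`: list(id, birth, sex).
quick_store <- function(persons, exposures = list(), measurements = list(),
                        conditions = list(), visits = list()) {
  v <- bundled_vocabulary()
  pdf <- do.call(rbind, lapply(persons, function(p) data.frame(
    person_id = p[[1]], birth_date = p[[2]], sex = p[[3]],
    ethnicity = NA, stringsAsFactors = FALSE)))
  edf <- if (length(exposures)) do.call(rbind, lapply(seq_along(exposures),
    function(i) {
      e <- exposures[[i]]
      data.frame(exposure_id = i, person_id = e[[1]], drug_concept_id = e[[2]],
                 start_datetime = e[[3]], end_datetime = e[[4]],
                 daily_dose_value = e$dose %||% NA,
                 daily_dose_unit = e$unit %||% NA,
                 route = e$route %||% "ORAL",
                 dose_direction = e$dir %||% NA, stringsAsFactors = FALSE)
    })) else NULL
  mdf <- if (length(measurements)) do.call(rbind, lapply(
    seq_along(measurements), function(i) {
      m <- measurements[[i]]
      data.frame(measurement_id = i, person_id = m[[1]],
                 measurement_concept_id = m[[2]], taken_datetime = m[[3]],
                 value = m[[4]], unit = m[[5]], stringsAsFactors = FALSE)
    })) else NULL
  cdf <- if (length(conditions)) do.call(rbind, lapply(conditions,
    function(cn) data.frame(person_id = cn[[1]], condition_concept_id = cn[[2]],
                            start_date = cn[[3]],
                            end_date = if (length(cn) > 3 && !is.na(cn[[4]]))
                              cn[[4]] else NA,
                            stringsAsFactors = FALSE))) else NULL
  vdf <- if (length(visits)) do.call(rbind, lapply(seq_along(visits),
    function(i) {
      vs <- visits[[i]]
      data.frame(visit_id = i, person_id = vs[[1]], start_datetime = vs[[2]],
                 end_datetime = vs[[3]],
                 visit_kind = if (length(vs) > 3) vs[[4]] else "UNKNOWN",
                 stringsAsFactors = FALSE)
    })) else NULL
  patient_store(person = pdf, drug_exposure = edf, measurement = mdf,
                condition_occurrence = cdf, visit_occurrence = vdf,
                concept = v$concept, concept_ancestor = v$concept_ancestor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolved_sets <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- resolve_concept_sets(bundled_concept_sets(),
                                     empty_patient_store())
    cache
  }
})

# a minimal one-predicate tree document for evaluator unit tests
mini_tree_doc <- function(comparator = "LT", threshold = 3.5,
                          missing_branch = "TRUE_BRANCH") {
  list(
    ddi_id = "mini", name = "mini",
    object_set = "potassium_supplements",
    precipitant_set = "k_sparing_diuretics",
    factors = list(list(name = "serum_potassium", type = "numeric",
                        extractor = "latest_lab",
                        params = list(set = "serum_potassium_lab",
                                      unit = "mEq/L"),
                        bounds = c(1, 9))),
    root = "n1",
    nodes = list(
      n1 = list(kind = "predicate", factor = "serum_potassium",
                comparator = comparator, threshold = threshold,
                missing_branch = missing_branch,
                true_branch = "leaf_t", false_branch = "leaf_f"),
      leaf_t = list(kind = "leaf", color = "RED"),
      leaf_f = list(kind = "leaf", color = "GREEN")))
}

severity_of <- function(tree, factors) {
  severity_rank(evaluate_tree(tree, factors)$color)
}

# full factor lattice over a tree's primitive factors: booleans take
# TRUE/FALSE, numerics two in-bounds values (plus NA when include_missing),
# enums their full domain
factor_lattice <- function(tree, include_missing = TRUE) {
  grids <- list()
  for (f in tree$factors) {
    if (identical(f$extractor, "risk_count")) next
    grids[[f$name]] <- switch(f$type,
      boolean = c(TRUE, FALSE),
      numeric = {
        b <- unlist(f$bounds)
        v <- c(b[1] + diff(b) * 0.25, b[1] + diff(b) * 0.75)
        if (include_missing) c(v, NA) else v
      },
      enum = unlist(f$domain))
  }
  do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
}

# monotonicity suite: flipping any declared boolean risk factor from absent
# to present never lowers severity; returns number of comparisons made
check_monotone <- function(tree) {
  grid <- factor_lattice(tree, include_missing = TRUE)
  n <- 0L
  for (r in seq_len(nrow(grid))) {
    base_vals <- as.list(grid[r, , drop = FALSE])
    base_sev <- severity_of(tree, base_vals)
    for (rf in tree$risk_factors) {
      if (isTRUE(base_vals[[rf]])) next
      flipped <- base_vals
      flipped[[rf]] <- TRUE
      n <- n + 1L
      if (severity_of(tree, flipped) < base_sev)
        return(list(ok = FALSE, n = n, at = base_vals, factor = rf))
    }
  }
  list(ok = TRUE, n = n)
}

# missing-data suite: masking any known factor to MISSING never lowers
# severity
check_missing_conservative <- function(tree) {
  grid <- factor_lattice(tree, include_missing = FALSE)
  n <- 0L
  for (r in seq_len(nrow(grid))) {
    base_vals <- as.list(grid[r, , drop = FALSE])
    base_sev <- severity_of(tree, base_vals)
    for (nm in names(base_vals)) {
      masked <- base_vals
      masked[[nm]] <- NA
      n <- n + 1L
      if (severity_of(tree, masked) < base_sev)
        return(list(ok = FALSE, n = n, at = base_vals, factor = nm))
    }
  }
  list(ok = TRUE, n = n)
}
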
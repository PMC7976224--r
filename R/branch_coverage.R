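# Branch-coverage population generation: for every leaf of a decision tree,
# synthesize one person whose single concomitant pair provably evaluates to
# that leaf. Works by enumerating root-to-leaf paths, solving the factor
# constraints along a path (numeric intervals, boolean/enum requirements,
# derived risk-count targets pushed down onto their boolean components), and
# materializing record-level events that make each extractor produce the
# solved value. A leaf with no satisfiable path is reported as unreachable,
# which doubles as a lint of hand-edited tree documents.

.tree_paths <- function(tree) {
  out <- list()
  walk <- function(id, constraints) {
    n <- tree$nodes[[id]]
    if (identical(n$kind, "leaf")) {
      out[[length(out) + 1L]] <<- list(leaf_id = id, constraints = constraints)
      return(invisible(NULL))
    }
    for (sat in c(TRUE, FALSE)) {
      c2 <- c(constraints, list(list(
        factor = n$factor, comparator = n$comparator,
        threshold = n$threshold %||% NULL,
        missing_branch = n$missing_branch, satisfied = sat)))
      walk(if (sat) n$true_branch else n$false_branch, c2)
    }
  }
  walk(tree$root, list())
  out
}

.factor_meta <- function(tree) {
  metas <- lapply(tree$factors, function(f) f)
  names(metas) <- vapply(tree$factors, `[[`, "", "name")
  metas
}

# can a MISSING value satisfy every constraint on this factor?
.missing_ok <- function(constraints) {
  all(vapply(constraints, function(cn) {
    if (cn$comparator == "PRESENT") return(!cn$satisfied)
    if (cn$comparator == "ABSENT") return(cn$satisfied)
    identical(cn$missing_branch == "TRUE_BRANCH", cn$satisfied)
  }, logical(1)))
}

.solve_numeric <- function(constraints, bounds) {
  lo <- bounds[1L]; hi <- bounds[2L]
  lo_open <- FALSE; hi_open <- FALSE
  must_be <- NULL; avoid <- numeric(0); need_present <- FALSE
  upd_hi <- function(x, open) {
    if (x < hi || (x == hi && open && !hi_open)) { hi <<- x; hi_open <<- open }
  }
  upd_lo <- function(x, open) {
    if (x > lo || (x == lo && open && !lo_open)) { lo <<- x; lo_open <<- open }
  }
  for (cn in constraints) {
    cmp <- cn$comparator; thr <- cn$threshold; sat <- cn$satisfied
    if (cmp %in% c("PRESENT", "ABSENT")) {
      if ((cmp == "PRESENT") == sat) need_present <- TRUE else return(NULL)
      next
    }
    need_present <- TRUE
    switch(cmp,
      LT = if (sat) upd_hi(thr, TRUE) else upd_lo(thr, FALSE),
      LE = if (sat) upd_hi(thr, FALSE) else upd_lo(thr, TRUE),
      GT = if (sat) upd_lo(thr, TRUE) else upd_hi(thr, FALSE),
      GE = if (sat) upd_lo(thr, FALSE) else upd_hi(thr, TRUE),
      EQ = if (sat) must_be <- thr else avoid <- c(avoid, thr),
      return(NULL))
  }
  inside <- function(x) {
    (x > lo || (!lo_open && x == lo)) && (x < hi || (!hi_open && x == hi)) &&
      !x %in% avoid
  }
  if (!is.null(must_be)) {
    if (inside(must_be)) return(must_be) else return(NULL)
  }
  cand <- c(if (!lo_open) lo, lo + (hi - lo) / 2, lo + (hi - lo) / 4,
            lo + 3 * (hi - lo) / 4, if (!hi_open) hi)
  for (x in cand) if (!is.na(x) && inside(x)) return(x)
  NULL
}

.solve_boolean <- function(constraints) {
  need <- c(TRUE, FALSE)
  for (cn in constraints) {
    if (cn$comparator %in% c("PRESENT", "ABSENT")) {
      if ((cn$comparator == "PRESENT") != cn$satisfied) return(NULL)
      next
    }
    if (cn$comparator != "EQ") return(NULL)
    want <- isTRUE(as.logical(cn$threshold)) == cn$satisfied
    need <- intersect(need, want)
  }
  if (length(need) == 0L) return(NULL)
  # prefer FALSE so unconstrained-looking persons stay benign
  if (FALSE %in% need) FALSE else TRUE
}

.solve_enum <- function(constraints, domain) {
  allowed <- domain
  for (cn in constraints) {
    if (cn$comparator %in% c("PRESENT", "ABSENT")) {
      if ((cn$comparator == "PRESENT") != cn$satisfied) return(NULL)
      next
    }
    vals <- if (cn$comparator == "EQ") cn$threshold
            else if (cn$comparator == "IN_SET") unlist(cn$threshold)
            else return(NULL)
    allowed <- if (cn$satisfied) intersect(allowed, vals)
               else setdiff(allowed, vals)
  }
  if (length(allowed) == 0L) NULL else allowed[[1L]]
}

# Solve one path's constraints into a complete primitive-factor assignment.
# Returns a named list (NA = deliberately missing) or NULL if unsatisfiable.
.solve_path <- function(tree, constraints) {
  metas <- .factor_meta(tree)
  by_factor <- split(constraints,
                     vapply(constraints, `[[`, "", "factor"))
  assign <- list()
  # pass 1: directly constrained factors
  for (nm in names(by_factor)) {
    f <- metas[[nm]]
    cns <- by_factor[[nm]]
    if (identical(f$extractor, "risk_count")) next
    v <- switch(f$type %||% "numeric",
                numeric = .solve_numeric(cns, unlist(f$bounds) %||% c(0, 1e6)),
                boolean = .solve_boolean(cns),
                enum = .solve_enum(cns, unlist(f$domain) %||% character(0)))
    if (is.null(v)) {
      if (!.missing_ok(cns)) return(NULL)
      v <- NA
    }
    assign[[nm]] <- v
  }
  # pass 2: risk-count factors -> choose how many components are present
  for (f in metas) {
    if (!identical(f$extractor, "risk_count")) next
    comp <- unlist(f$params$components)
    if (any(comp %in% names(by_factor)))
      stop("tree '", tree$ddi_id, "': risk-count components may not be ",
           "constrained directly on the same path")
    cns <- by_factor[[f$name]] %||% list()
    k <- .solve_numeric(cns, c(0, length(comp)))
    if (is.null(k)) return(NULL)
    k <- ceiling(k - 1e-9)
    assign[comp[seq_along(comp) <= k]] <- TRUE
    assign[comp[seq_along(comp) > k]] <- FALSE
  }
  # pass 3: benign defaults for untouched primitive factors (so that, e.g.,
  # an unmeasured lab cannot steer a node that is not on this path)
  for (f in metas) {
    if (identical(f$extractor, "risk_count") || f$name %in% names(assign))
      next
    assign[[f$name]] <- switch(f$type %||% "numeric",
                               boolean = FALSE,
                               numeric = NA,
                               enum = NA)
  }
  assign
}

# Materialize one person realizing a factor assignment for a tree. The
# trigger pair is an object exposure [T-1d, T+3d] and a precipitant exposure
# [T, T+3d]; factor planting then edits concepts, routes, doses, end times
# and adds the supporting labs/conditions/visits.
.materialize_person <- function(b, tree, assign, sets, anc, trigger) {
  metas <- .factor_meta(tree)
  t0 <- .ts(trigger)
  day <- as.Date(t0, tz = "UTC")

  sex <- if (isTRUE(assign$female_sex)) "FEMALE" else "MALE"
  age <- 50
  obj_concept <- .rep_member(sets[[tree$object_set]], anc)
  prec_concept <- .rep_member(sets[[tree$precipitant_set]], anc)
  obj <- list(concept = obj_concept, start = t0 - 86400, end = t0 + 3 * 86400,
              dose = NA, unit = NA, route = "ORAL")
  prec <- list(concept = prec_concept, start = t0, end = t0 + 3 * 86400,
               dose = NA, unit = NA, route = "ORAL")
  extras <- list(labs = list(), conds = list(), drugs = list(),
                 visits = list())

  side <- function(which) if (identical(which, "precipitant")) "prec" else "obj"
  get_side <- function(which) if (side(which) == "prec") prec else obj
  set_side <- function(which, val) {
    if (side(which) == "prec") prec <<- val else obj <<- val
  }

  plant <- function(f, v) {
    p <- f$params %||% list()
    switch(f$extractor,
      sex_female = { sex <<- if (isTRUE(v)) "FEMALE" else "MALE" },
      age = if (!is.na(v)) age <<- v,
      age_flag = { age <<- if (isTRUE(v)) p$threshold + 2 else
                            max(25, p$threshold - 10) },
      latest_lab = if (!all(is.na(v)))
        extras$labs[[length(extras$labs) + 1L]] <<-
          list(concept = .rep_member(sets[[p$set]], anc), value = v,
               unit = p$unit %||% ""),
      lab_flag = {
        if (all(is.na(v))) return(invisible(NULL))
        thr <- p$threshold
        val <- switch(p$comparator,
                      LT = if (isTRUE(v)) thr - 0.7 else thr + 0.7,
                      LE = if (isTRUE(v)) thr else thr + 0.7,
                      GT = if (isTRUE(v)) thr + 0.7 else thr,
                      GE = if (isTRUE(v)) thr else thr - 0.7)
        extras$labs[[length(extras$labs) + 1L]] <<-
          list(concept = .rep_member(sets[[p$set]], anc), value = val,
               unit = p$unit %||% "")
      },
      condition = if (isTRUE(v))
        extras$conds[[length(extras$conds) + 1L]] <<-
          list(concept = .rep_member(sets[[p$set]], anc)),
      concomitant_drug = if (isTRUE(v))
        extras$drugs[[length(extras$drugs) + 1L]] <<-
          list(concept = .rep_member(sets[[p$set]], anc)),
      drug_class = {
        if (all(is.na(v))) return(invisible(NULL))
        for (cl in p$classes) if (identical(cl$label, v)) {
          s <- get_side(p$which %||% "precipitant")
          s$concept <- .rep_member(sets[[cl$set]], anc)
          set_side(p$which %||% "precipitant", s)
        }
      },
      drug_route = if (!all(is.na(v))) {
        s <- get_side(p$which %||% "object"); s$route <- v
        set_side(p$which %||% "object", s)
      },
      drug_route_in = if (isTRUE(v)) {
        s <- get_side(p$which %||% "precipitant")
        s$concept <- .rep_member(sets[[p$set]], anc)
        s$route <- unlist(p$routes)[1L]
        set_side(p$which %||% "precipitant", s)
      },
      daily_dose = if (!all(is.na(v))) {
        s <- get_side(p$which %||% "object")
        s$dose <- v; s$unit <- p$unit %||% "mg/day"
        set_side(p$which %||% "object", s)
      },
      withdrawal = if (isTRUE(v)) {
        obj$end <<- t0 + 2 * 86400
        prec$end <<- t0 + 6 * 86400
      } else {
        obj$end <<- max(obj$end, prec$end)
      },
      inpatient = if (isTRUE(v))
        extras$visits[[length(extras$visits) + 1L]] <<-
          list(start = t0 - 86400, end = t0 + 2 * 86400, kind = "INPATIENT"),
      risk_count = invisible(NULL),
      stop("no planting rule for extractor '", f$extractor, "'"))
    invisible(NULL)
  }

  ord <- order(vapply(metas, function(f) switch(f$extractor,
    drug_class = 1L, drug_route_in = 2L, 3L), integer(1)))
  for (f in metas[ord]) plant(f, assign[[f$name]])

  pid <- length(b$person) + 1L
  birth <- day - round(age * 365.2425 + 180)
  .add_person(b, pid, birth, sex)
  .add_exposure(b, pid, obj$concept, obj$start, obj$end, dose = obj$dose,
                dose_unit = obj$unit, route = obj$route)
  .add_exposure(b, pid, prec$concept, prec$start, prec$end, dose = prec$dose,
                dose_unit = prec$unit, route = prec$route)
  for (x in extras$labs)
    .add_measurement(b, pid, x$concept, t0 - 3600, x$value, x$unit)
  for (x in extras$conds)
    .add_condition(b, pid, x$concept, day - 30)
  for (x in extras$drugs)
    .add_exposure(b, pid, x$concept, t0 - 2 * 86400, t0 + 2 * 86400)
  for (x in extras$visits)
    .add_visit(b, pid, x$start, x$end, x$kind)
  pid
}

#' Generate a branch-coverage population for one decision tree
#'
#' For every leaf of the tree, synthesizes one person whose single
#' concomitant pair evaluates to exactly that leaf, and attaches a manifest
#' mapping person to expected leaf. The generated store is self-verified:
#' the tree is executed against it and any disagreement with the manifest
#' aborts. A leaf that no factor assignment can reach raises a generation
#' error naming the leaf.
#'
#' @param tree A `ddi_tree`.
#' @param seed Integer; the construction is deterministic, the argument is
#'   accepted for interface uniformity.
#' @param config A `context_config` used for the self-verification run.
#' @return A `patient_store` with attribute `"manifest"`: a data frame with
#'   columns `person_id`, `leaf_id`.
#' @export
generate_branch_coverage <- function(tree, seed = 1L,
                                     config = context_config()) {
  stopifnot(inherits(tree, "ddi_tree"))
  base <- empty_patient_store()
  sets <- resolve_concept_sets(bundled_concept_sets(), base)
  anc <- base$concept_ancestor
  paths <- .tree_paths(tree)
  leaves <- tree_leaves(tree)$leaf_id
  b <- .new_builder()
  manifest <- list()
  for (i in seq_along(leaves)) {
    leaf <- leaves[i]
    solved <- NULL
    for (pth in paths) {
      if (!identical(pth$leaf_id, leaf)) next
      solved <- .solve_path(tree, pth$constraints)
      if (!is.null(solved)) break
    }
    if (is.null(solved))
      stop("tree '", tree$ddi_id, "': leaf '", leaf,
           "' is unreachable under its factor manifest")
    trigger <- sprintf("2016-02-%02dT12:00:00Z", i)
    pid <- .materialize_person(b, tree, solved, sets, anc, trigger)
    manifest[[length(manifest) + 1L]] <- data.frame(
      person_id = pid, leaf_id = leaf, stringsAsFactors = FALSE)
  }
  store <- .build_store(b)
  manifest <- do.call(rbind, manifest)
  # self-verification: the engine must reproduce the manifest exactly,
  # with exactly one pair per person
  sets_full <- resolve_concept_sets(bundled_concept_sets(), store)
  events <- run_algorithm(store, tree, config, sets_full)
  got <- events$leaf_id[match(manifest$person_id, events$person_id)]
  if (nrow(events) != nrow(manifest) || any(is.na(got)) ||
      !identical(got, manifest$leaf_id))
    stop("tree '", tree$ddi_id,
         "': branch-coverage self-verification failed")
  attr(store, "manifest") <- manifest
  store
}
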
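#' Operational classification colors
#'
#' The fixed three-color leaf scheme and its clinical recommendations:
#' Red "Avoid Combination", Yellow "Usually Avoid Combination or Minimize
#' Risk", Green "No Special Precautions". Green is the class of alerts a
#' contextualized system would filter out of the interruptive workflow.
#' @format Named character vector keyed by color.
#' @export
leaf_recommendations <- c(
  RED = "Avoid Combination",
  YELLOW = "Usually Avoid Combination or Minimize Risk",
  GREEN = "No Special Precautions")

#' Severity rank of the classification colors
#'
#' `RED` (3) > `YELLOW` (2) > `GREEN` (1); used by the monotonicity
#' property checks.
#' @param color Character vector of colors.
#' @return Integer severity ranks.
#' @export
severity_rank <- function(color) {
  unname(c(GREEN = 1L, YELLOW = 2L, RED = 3L)[color])
}

.comparators <- c("LT", "LE", "GT", "GE", "EQ", "IN_SET", "PRESENT", "ABSENT")

#' Parse a decision-tree document
#'
#' Tree documents are JSON: identification (`ddi_id`, `name`), the object
#' and precipitant concept-set ids, a factor manifest (`factors`: name,
#' type, extractor, params, optional enumeration domain and numeric
#' bounds), the node table (`nodes`: predicate nodes with factor,
#' comparator, threshold and a `missing_branch`; leaf nodes with a color),
#' the `root` node id, a `monotone_severity` flag and the list of boolean
#' `risk_factors` the monotonicity property ranges over. Parsing validates
#' the structural invariants: the node graph is a rooted tree (acyclic,
#' single parent, every path ending at a leaf), every referenced factor is
#' declared, every leaf color carries its fixed recommendation, and
#' comparators are from the supported vocabulary.
#'
#' @param path Path to a JSON tree document.
#' @return An object of class `ddi_tree`.
#' @export
read_ddi_tree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_ddi_tree(doc)
}

#' @rdname read_ddi_tree
#' @param doc A tree document already deserialized to an R list.
#' @export
parse_ddi_tree <- function(doc) {
  for (fld in c("ddi_id", "object_set", "precipitant_set", "root", "nodes",
                "factors"))
    if (is.null(doc[[fld]])) stop("tree document lacks field '", fld, "'")
  factors <- lapply(doc$factors, function(f) {
    if (is.null(f$name) || is.null(f$extractor))
      stop("tree '", doc$ddi_id, "': factor without name/extractor")
    f$params <- lapply(f$params %||% list(), function(p)
      if (is.list(p)) p else unlist(p))
    f
  })
  factor_names <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(factor_names))
    stop("tree '", doc$ddi_id, "': duplicate factor names")

  nodes <- doc$nodes
  for (id in names(nodes)) {
    n <- nodes[[id]]
    if (identical(n$kind, "leaf")) {
      if (is.null(n$color) || !n$color %in% names(leaf_recommendations))
        stop("tree '", doc$ddi_id, "': leaf '", id, "' has invalid color")
      rec <- n$recommendation %||% leaf_recommendations[[n$color]]
      if (!identical(rec, leaf_recommendations[[n$color]]))
        stop("tree '", doc$ddi_id, "': leaf '", id,
             "' recommendation does not match its color")
      nodes[[id]]$recommendation <- rec
    } else if (identical(n$kind, "predicate")) {
      if (is.null(n$factor) || !n$factor %in% factor_names)
        stop("tree '", doc$ddi_id, "': node '", id,
             "' references undeclared factor '", n$factor %||% "?", "'")
      if (is.null(n$comparator) || !n$comparator %in% .comparators)
        stop("tree '", doc$ddi_id, "': node '", id, "' has invalid comparator")
      for (br in c("true_branch", "false_branch"))
        if (is.null(n[[br]]) || !n[[br]] %in% names(nodes))
          stop("tree '", doc$ddi_id, "': node '", id, "' has dangling ", br)
      if (is.null(n$missing_branch))
        nodes[[id]]$missing_branch <- "TRUE_BRANCH"
      if (!nodes[[id]]$missing_branch %in% c("TRUE_BRANCH", "FALSE_BRANCH"))
        stop("tree '", doc$ddi_id, "': node '", id, "' invalid missing_branch")
    } else stop("tree '", doc$ddi_id, "': node '", id, "' has invalid kind")
  }
  if (!doc$root %in% names(nodes))
    stop("tree '", doc$ddi_id, "': root node '", doc$root, "' not found")

  # rooted-tree check: walk from root; each node reached once (single
  # parent), no cycles, all nodes reachable, every path ends at a leaf
  parent_seen <- character(0)
  stack <- doc$root
  while (length(stack)) {
    id <- stack[[1L]]; stack <- stack[-1L]
    if (id %in% parent_seen)
      stop("tree '", doc$ddi_id, "': node '", id,
           "' reached twice (cycle or multiple parents)")
    parent_seen <- c(parent_seen, id)
    n <- nodes[[id]]
    if (identical(n$kind, "predicate"))
      stack <- c(stack, n$true_branch, n$false_branch)
  }
  unreachable <- setdiff(names(nodes), parent_seen)
  if (length(unreachable))
    stop("tree '", doc$ddi_id, "': unreachable node(s): ",
         paste(unreachable, collapse = ", "))

  structure(list(
    ddi_id = doc$ddi_id,
    name = doc$name %||% doc$ddi_id,
    object_set = doc$object_set,
    precipitant_set = doc$precipitant_set,
    monotone_severity = isTRUE(doc$monotone_severity),
    risk_factors = unlist(doc$risk_factors) %||% character(0),
    factors = factors,
    root = doc$root,
    nodes = nodes), class = "ddi_tree")
}

#' @export
print.ddi_tree <- function(x, ...) {
  leaves <- tree_leaves(x)
  cat(sprintf("<ddi_tree> %s (%s x %s): %d nodes, %d leaves (%s)\n",
              x$ddi_id, x$object_set, x$precipitant_set, length(x$nodes),
              nrow(leaves), paste(leaves$color, collapse = "/")))
  invisible(x)
}

#' List the leaves of a decision tree
#'
#' @param tree A `ddi_tree`.
#' @return Data frame with `leaf_id`, `color`, `recommendation`.
#' @export
tree_leaves <- function(tree) {
  ids <- names(tree$nodes)[vapply(tree$nodes, function(n)
    identical(n$kind, "leaf"), logical(1))]
  data.frame(leaf_id = ids,
             color = vapply(tree$nodes[ids], `[[`, "", "color"),
             recommendation = vapply(tree$nodes[ids], `[[`, "", "recommendation"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Load the bundled decision-tree documents
#'
#' Reads the eight DDI algorithm documents shipped under `inst/rules/`.
#' Thresholds, dose tiers and windows in these documents are named
#' defaults intended to be reconciled against a site's own clinical
#' review; they are data, not code.
#'
#' @param dir Directory of tree documents; defaults to the bundled ones.
#' @return Named list of `ddi_tree` objects keyed by `ddi_id`.
#' @export
bundled_trees <- function(dir = system.file("rules", package = "ddialert")) {
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  trees <- lapply(paths, read_ddi_tree)
  names(trees) <- vapply(trees, `[[`, "", "ddi_id")
  if (anyDuplicated(names(trees)))
    stop("duplicate ddi_id among tree documents in ", dir)
  trees
}

.apply_comparator <- function(value, comparator, threshold) {
  missing <- length(value) == 0L || all(is.na(value))
  if (comparator == "PRESENT") return(!missing)
  if (comparator == "ABSENT") return(missing)
  if (missing) return(NA)
  switch(comparator,
         LT = value < threshold,
         LE = value <= threshold,
         GT = value > threshold,
         GE = value >= threshold,
         EQ = if (is.logical(value) || is.logical(threshold))
           isTRUE(value) == isTRUE(as.logical(threshold))
         else value == threshold,
         IN_SET = value %in% unlist(threshold),
         stop("unsupported comparator: ", comparator))
}

#' Evaluate a decision tree on a patient context
#'
#' Deterministic descent from the root: each predicate node compares the
#' named factor value against its threshold; a MISSING value follows the
#' node's declared `missing_branch`; descent stops at the unique leaf
#' reached.
#'
#' @param tree A `ddi_tree`.
#' @param context A `patient_context` from [build_context()], or a named
#'   list of factor values (primitive values are completed through
#'   [evaluate_factors()]).
#' @return List with `leaf_id`, `color`, `recommendation` and `path`
#'   (ordered node ids from root to leaf).
#' @export
evaluate_tree <- function(tree, context) {
  values <- if (inherits(context, "patient_context")) context$factor_values
            else evaluate_factors(tree, context)
  id <- tree$root
  path <- character(0)
  repeat {
    path <- c(path, id)
    n <- tree$nodes[[id]]
    if (identical(n$kind, "leaf"))
      return(list(leaf_id = id, color = n$color,
                  recommendation = n$recommendation, path = path))
    v <- values[[n$factor]]
    res <- .apply_comparator(v, n$comparator, n$threshold)
    if (is.na(res))
      res <- identical(n$missing_branch, "TRUE_BRANCH")
    if (!is.logical(res) || length(res) != 1L)
      stop("tree '", tree$ddi_id, "': node '", id,
           "': type mismatch between factor '", n$factor, "' and threshold")
    id <- if (res) n$true_branch else n$false_branch
  }
}

#' Run one DDI algorithm over a store
#'
#' Detects every basic concomitant exposure between the tree's object and
#' precipitant drug sets, extracts the patient context at each trigger
#' time, and classifies it through the decision tree. Exactly one alert
#' event is produced per concomitant pair.
#'
#' @param store A `patient_store`.
#' @param tree A `ddi_tree`.
#' @param config A `context_config`.
#' @param sets Named list of resolved concept sets; defaults to resolving
#'   the bundled definitions against `store`.
#' @return Data frame of alert events sorted by person and trigger time:
#'   `ddi_id`, `person_id`, `trigger_datetime`, `object_exposure_id`,
#'   `precipitant_exposure_id`, `leaf_id`, `color`, `recommendation`,
#'   `path` (node ids joined by `">"`). The per-pair `patient_context`
#'   snapshots are attached as attribute `"contexts"`.
#' @export
run_algorithm <- function(store, tree, config = context_config(),
                          sets = NULL) {
  if (is.null(sets))
    sets <- resolve_concept_sets(bundled_concept_sets(), store)
  for (sid in c(tree$object_set, tree$precipitant_set))
    if (is.null(sets[[sid]]))
      stop("tree '", tree$ddi_id, "': concept set '", sid,
           "' is not resolvable")
  pairs <- find_concomitant_pairs(store, sets[[tree$object_set]],
                                  sets[[tree$precipitant_set]])
  n <- nrow(pairs)
  events <- data.frame(
    ddi_id = rep(tree$ddi_id, n), person_id = pairs$person_id,
    trigger_datetime = pairs$trigger_datetime,
    object_exposure_id = pairs$object_exposure_id,
    precipitant_exposure_id = pairs$precipitant_exposure_id,
    leaf_id = character(n), color = character(n),
    recommendation = character(n), path = character(n),
    stringsAsFactors = FALSE)
  contexts <- vector("list", n)
  for (i in seq_len(n)) {
    ctx <- build_context(store, pairs[i, , drop = FALSE], tree, config, sets)
    res <- evaluate_tree(tree, ctx)
    events$leaf_id[i] <- res$leaf_id
    events$color[i] <- res$color
    events$recommendation[i] <- res$recommendation
    events$path[i] <- paste(res$path, collapse = ">")
    contexts[[i]] <- ctx
  }
  attr(events, "contexts") <- contexts
  events
}
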
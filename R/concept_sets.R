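#' Define a concept set
#'
#' A concept set names a clinical entity (a drug class, a laboratory test, a
#' family of conditions) as an extensional collection of terminology
#' concepts. Sets are authored the way value-set registries publish them:
#' seed concepts from one vocabulary, an optional instruction to pull in all
#' descendants through the concept ancestry, and explicit exclusions removed
#' after descendant assembly.
#'
#' @param set_id Short stable identifier (used by decision-tree documents).
#' @param name Human-readable name.
#' @param vocabulary One of `"RXNORM"`, `"LOINC"`, `"SNOMED"`.
#' @param seed_concept_ids Non-empty integer vector of seed concepts.
#' @param include_descendants Pull in all transitive descendants of the
#'   seeds through the store's ancestry (default `FALSE`).
#' @param excluded_concept_ids Concepts removed from the final membership.
#' @return An object of class `concept_set_definition`.
#' @export
concept_set_definition <- function(set_id, name, vocabulary, seed_concept_ids,
                                   include_descendants = FALSE,
                                   excluded_concept_ids = integer(0)) {
  stopifnot(is.character(set_id), length(set_id) == 1L, nzchar(set_id))
  if (!vocabulary %in% .vocab_levels)
    stop("vocabulary must be one of ", paste(.vocab_levels, collapse = "/"))
  seeds <- as.integer(seed_concept_ids)
  if (length(seeds) == 0L || anyNA(seeds))
    stop("concept set '", set_id, "': seed list must be non-empty")
  structure(list(set_id = set_id, name = name, vocabulary = vocabulary,
                 seed_concept_ids = seeds,
                 include_descendants = isTRUE(include_descendants),
                 excluded_concept_ids = as.integer(excluded_concept_ids)),
            class = "concept_set_definition")
}

#' Read a concept-set definition document
#'
#' Concept-set documents are JSON files with fields `set_id`, `name`,
#' `vocabulary`, `seed_concept_ids`, `include_descendants` and
#' `excluded_concept_ids`, one file per set (see the bundled documents under
#' `inst/concept_sets/` for the dialect).
#'
#' @param path Path to a JSON concept-set document.
#' @return A `concept_set_definition`.
#' @export
read_concept_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("set_id", "name", "vocabulary", "seed_concept_ids")
  miss <- setdiff(required, names(doc))
  if (length(miss))
    stop("concept-set document ", path, " lacks field(s): ",
         paste(miss, collapse = ", "))
  concept_set_definition(doc$set_id, doc$name, doc$vocabulary,
                         doc$seed_concept_ids,
                         isTRUE(doc$include_descendants),
                         doc$excluded_concept_ids %||% integer(0))
}

# transitive descendants of `ids` over the direct parent->child edge table
.descendants <- function(ids, ancestry) {
  out <- integer(0)
  frontier <- unique(ids)
  while (length(frontier) > 0L) {
    nxt <- ancestry$descendant_concept_id[
      ancestry$ancestor_concept_id %in% frontier]
    nxt <- setdiff(unique(nxt), c(out, ids))
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Resolve a concept-set definition against a store's vocabulary
#'
#' Membership is the seed set, plus (when `include_descendants` is set) all
#' transitive descendants reachable through the store's `concept_ancestor`
#' table, minus the exclusions. Resolution is a pure function of the
#' definition and the ancestry: repeated calls yield identical membership.
#'
#' @param definition A `concept_set_definition`.
#' @param store A `patient_store` whose `concept` table contains every seed.
#' @return An object of class `resolved_concept_set` with fields `set_id`
#'   and `member_concept_ids` (sorted, duplicate-free).
#' @export
resolve_concept_set <- function(definition, store) {
  stopifnot(inherits(definition, "concept_set_definition"),
            inherits(store, "patient_store"))
  unknown <- setdiff(definition$seed_concept_ids, store$concept$concept_id)
  if (length(unknown))
    stop("concept set '", definition$set_id, "': unknown seed concept id(s): ",
         paste(unknown, collapse = ", "))
  members <- definition$seed_concept_ids
  if (definition$include_descendants)
    members <- c(members, .descendants(members, store$concept_ancestor))
  members <- sort(setdiff(unique(members), definition$excluded_concept_ids))
  if (length(members) == 0L)
    stop("concept set '", definition$set_id,
         "': empty membership after exclusions")
  structure(list(set_id = definition$set_id,
                 member_concept_ids = as.integer(members)),
            class = "resolved_concept_set")
}

#' Test membership in a resolved concept set
#'
#' Non-membership (including identifiers absent from the vocabulary
#' entirely) is `FALSE`, never an error.
#'
#' @param concept_id Integer concept identifier(s).
#' @param resolved A `resolved_concept_set` from [resolve_concept_set()].
#' @return Logical vector, `TRUE` where the id is a member.
#' @export
is_member <- function(concept_id, resolved) {
  stopifnot(inherits(resolved, "resolved_concept_set"))
  as.integer(concept_id) %in% resolved$member_concept_ids
}

#' Load the bundled concept-set definitions
#'
#' Reads every concept-set document shipped with the package (synthetic
#' stand-ins for the published value sets, sized to the bundled vocabulary;
#' real registry set identifiers can be swapped in by editing the
#' documents).
#'
#' @param dir Directory of concept-set documents; defaults to the bundled
#'   ones.
#' @return Named list of `concept_set_definition` objects keyed by `set_id`.
#' @export
bundled_concept_sets <- function(dir = system.file("concept_sets",
                                                   package = "ddialert")) {
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  paths <- paths[basename(paths) != "manifest.json"]
  defs <- lapply(paths, read_concept_set)
  names(defs) <- vapply(defs, `[[`, "", "set_id")
  if (anyDuplicated(names(defs)))
    stop("duplicate set_id among concept-set documents in ", dir)
  defs
}

#' Read the bundled concept-set manifest
#'
#' The manifest lists, per DDI algorithm, the concept sets its decision tree
#' relies on; [audit_coverage()] checks it against the bundled trees.
#'
#' @param path Manifest path; defaults to the bundled manifest.
#' @return Named list mapping `ddi_id` to a character vector of set ids.
#' @export
concept_set_manifest <- function(path = system.file("concept_sets",
                                                    "manifest.json",
                                                    package = "ddialert")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Resolve many concept sets at once
#'
#' @param definitions Named list of `concept_set_definition` objects.
#' @param store A `patient_store`.
#' @return Named list of `resolved_concept_set` objects keyed by `set_id`
#'   (the resolution cache handed to the rule engine).
#' @export
resolve_concept_sets <- function(definitions, store) {
  out <- lapply(definitions, resolve_concept_set, store = store)
  names(out) <- vapply(out, `[[`, "", "set_id")
  out
}
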
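#' Run all DDI algorithms and aggregate a report
#'
#' Executes every tree against the store and assembles the per-DDI
#' aggregates that mirror the two-bar reading of an alert-burden figure:
#' the basic concomitant-exposure count (what an uncontextualized system
#' would fire), the per-leaf and per-color breakdown of the classified
#' alerts, and the filtered fraction — the share of basic exposures the
#' algorithm classifies "No Special Precautions" and would therefore keep
#' out of the interruptive workflow.
#'
#' @param store A `patient_store`.
#' @param trees Non-empty named list of `ddi_tree` objects (distinct
#'   `ddi_id`s).
#' @param config A `context_config`.
#' @param sets Optional pre-resolved concept sets.
#' @return An object of class `ddi_run_report`: list with `per_ddi` (one
#'   row per DDI: `ddi_id`, `n_basic_concomitant`, `n_red`, `n_yellow`,
#'   `n_green`, `filtered_fraction`), `leaf_counts` (`ddi_id`, `leaf_id`,
#'   `color`, `n`), and `events` (all alert events).
#' @export
run_all <- function(store, trees = bundled_trees(),
                    config = context_config(), sets = NULL) {
  if (length(trees) == 0L) stop("trees must be non-empty")
  ids <- vapply(trees, `[[`, "", "ddi_id")
  if (anyDuplicated(ids)) stop("duplicate ddi_id among trees")
  if (is.null(sets))
    sets <- resolve_concept_sets(bundled_concept_sets(), store)
  ev_list <- lapply(trees, run_algorithm, store = store, config = config,
                    sets = sets)
  events <- do.call(rbind, lapply(ev_list, function(e) {
    attr(e, "contexts") <- NULL; e
  }))
  rownames(events) <- NULL
  per_ddi <- do.call(rbind, lapply(seq_along(trees), function(i) {
    e <- ev_list[[i]]
    n <- nrow(e)
    ng <- sum(e$color == "GREEN")
    data.frame(ddi_id = ids[i], n_basic_concomitant = n,
               n_red = sum(e$color == "RED"),
               n_yellow = sum(e$color == "YELLOW"), n_green = ng,
               filtered_fraction = if (n == 0L) 0 else ng / n,
               stringsAsFactors = FALSE)
  }))
  leaf_counts <- do.call(rbind, lapply(seq_along(trees), function(i) {
    lv <- tree_leaves(trees[[i]])
    e <- ev_list[[i]]
    data.frame(ddi_id = ids[i], leaf_id = lv$leaf_id, color = lv$color,
               n = vapply(lv$leaf_id, function(l) sum(e$leaf_id == l),
                          integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(per_ddi) <- rownames(leaf_counts) <- NULL
  structure(list(per_ddi = per_ddi, leaf_counts = leaf_counts,
                 events = events),
            class = "ddi_run_report")
}

#' Summary table of a run report
#'
#' One row per DDI plus an overall total row; color percentages are
#' recomputed from the counts at print time (one decimal place), never
#' stored. The conservation identity (per-color counts summing to the
#' basic concomitant count for every DDI) is asserted before the table is
#' built.
#'
#' @param report A `ddi_run_report`.
#' @return Data frame with counts, percentages and filtered fractions.
#' @export
summary_table <- function(report) {
  stopifnot(inherits(report, "ddi_run_report"))
  p <- report$per_ddi
  stopifnot(all(p$n_red + p$n_yellow + p$n_green == p$n_basic_concomitant))
  lc <- report$leaf_counts
  agg <- vapply(split(lc$n, lc$ddi_id), sum, integer(1))
  stopifnot(all(agg[p$ddi_id] == p$n_basic_concomitant))
  tot <- data.frame(ddi_id = "TOTAL",
                    n_basic_concomitant = sum(p$n_basic_concomitant),
                    n_red = sum(p$n_red), n_yellow = sum(p$n_yellow),
                    n_green = sum(p$n_green),
                    filtered_fraction = if (sum(p$n_basic_concomitant) == 0L) 0
                    else sum(p$n_green) / sum(p$n_basic_concomitant),
                    stringsAsFactors = FALSE)
  out <- rbind(p, tot)
  pct <- function(n) ifelse(out$n_basic_concomitant == 0L, 0,
                            round(100 * n / out$n_basic_concomitant, 1))
  out$pct_red <- pct(out$n_red)
  out$pct_yellow <- pct(out$n_yellow)
  out$pct_green <- pct(out$n_green)
  rownames(out) <- NULL
  out
}

#' @export
print.ddi_run_report <- function(x, ...) {
  s <- summary_table(x)
  cat("<ddi_run_report>\n")
  cat(sprintf("  %-32s %6s %5s %7s %6s %9s\n",
              "ddi_id", "basic", "red", "yellow", "green", "filtered%"))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-32s %6d %5d %7d %6d %8.1f%%\n", s$ddi_id[i],
                s$n_basic_concomitant[i], s$n_red[i], s$n_yellow[i],
                s$n_green[i], 100 * s$filtered_fraction[i]))
  invisible(x)
}

#' Serialize a run report
#'
#' Writes the machine-readable report (JSON: per-DDI aggregates, per-leaf
#' counts and the event list) and a human-readable tab-separated summary
#' table alongside it.
#'
#' @param report A `ddi_run_report`.
#' @param path Output JSON path; the summary table is written next to it
#'   with a `.tsv` extension.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  ev <- report$events
  ev$trigger_datetime <- .format_ts(ev$trigger_datetime)
  jsonlite::write_json(list(per_ddi = report$per_ddi,
                            leaf_counts = report$leaf_counts, events = ev),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(summary_table(report), sub("\\.json$", ".tsv", path),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-DDI daily alert counts from a run report
#'
#' Groups the engine's alert events by the calendar date (UTC) of their
#' trigger time — the granularity at which independently written database
#' queries are compared with the rule engine during validation. Basic and
#' per-color counts are both reported.
#'
#' @param report A `ddi_run_report`.
#' @return Data frame `ddi_id`, `date`, `n_basic`, `n_red`, `n_yellow`,
#'   `n_green`, sorted by DDI and date.
#' @export
engine_daily_counts <- function(report) {
  stopifnot(inherits(report, "ddi_run_report"))
  e <- report$events
  .daily_count_frame(e$ddi_id, as.Date(e$trigger_datetime, tz = "UTC"),
                     e$color, unique(report$per_ddi$ddi_id))
}

# shared tabulation of (ddi, date, color) triples into the daily-count frame
.daily_count_frame <- function(ddi_id, date, color, all_ddis) {
  if (length(ddi_id) == 0L)
    return(data.frame(ddi_id = character(0), date = as.Date(character(0)),
                      n_basic = integer(0), n_red = integer(0),
                      n_yellow = integer(0), n_green = integer(0)))
  key <- paste(ddi_id, date)
  idx <- !duplicated(key)
  out <- data.frame(ddi_id = ddi_id[idx], date = date[idx],
                    stringsAsFactors = FALSE)
  cnt <- function(sel) vapply(which(idx), function(i)
    sum(key == key[i] & sel), integer(1))
  out$n_basic <- cnt(rep(TRUE, length(key)))
  out$n_red <- cnt(color == "RED")
  out$n_yellow <- cnt(color == "YELLOW")
  out$n_green <- cnt(color == "GREEN")
  out <- out[order(out$ddi_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}
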
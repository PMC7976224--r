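test_that("tree parsing enforces the structural invariants", {
  # single-leaf tree is valid and classifies everything green
  doc <- list(ddi_id = "solo", object_set = "warfarin",
              precipitant_set = "aspirin", factors = list(),
              root = "l1",
              nodes = list(l1 = list(kind = "leaf", color = "GREEN")))
  tree <- parse_ddi_tree(doc)
  res <- evaluate_tree(tree, list())
  expect_equal(res$color, "GREEN")
  expect_equal(res$recommendation, "No Special Precautions")

  # undeclared factor is named in the error
  bad <- mini_tree_doc()
  bad$nodes$n1$factor <- "qtc"
  expect_error(parse_ddi_tree(bad), "qtc")

  # dangling branch
  bad2 <- mini_tree_doc()
  bad2$nodes$n1$true_branch <- "nowhere"
  expect_error(parse_ddi_tree(bad2), "dangling")

  # cycle / multiple parents
  bad3 <- mini_tree_doc()
  bad3$nodes$n1$false_branch <- "n1"
  expect_error(parse_ddi_tree(bad3), "twice")

  # a leaf whose recommendation contradicts its color is rejected
  bad4 <- mini_tree_doc()
  bad4$nodes$leaf_t$recommendation <- "No Special Precautions"
  expect_error(parse_ddi_tree(bad4), "recommendation")
})

test_that("all eight bundled documents parse with distinct identities", {
  trees <- bundled_trees()
  expect_length(trees, 8L)
  expect_length(unique(names(trees)), 8L)
  for (tree in trees) {
    lv <- tree_leaves(tree)
    expect_true(all(lv$recommendation ==
                      leaf_recommendations[lv$color]))
    # every tree except epinephrine/beta-blocker has a green leaf
    if (tree$ddi_id != "epinephrine_beta_blocker")
      expect_true("GREEN" %in% lv$color, label = tree$ddi_id)
    expect_true(any(lv$color != "GREEN"), label = tree$ddi_id)
  }
})

test_that("predicate comparison semantics: thresholds inclusive where declared", {
  tree <- parse_ddi_tree(mini_tree_doc("LT", 3.5))
  expect_equal(evaluate_tree(tree, list(serum_potassium = 3.2))$color, "RED")
  expect_equal(evaluate_tree(tree, list(serum_potassium = 3.5))$color, "GREEN")

  # age >= 68 is satisfied at exactly 68
  doc <- mini_tree_doc("GE", 68)
  doc$factors[[1]] <- list(name = "age_years", type = "numeric",
                           extractor = "age", bounds = c(0, 110))
  doc$nodes$n1$factor <- "age_years"
  aged <- parse_ddi_tree(doc)
  expect_equal(evaluate_tree(aged, list(age_years = 68))$color, "RED")
  expect_equal(evaluate_tree(aged, list(age_years = 67))$color, "GREEN")
})

test_that("MISSING values follow the declared missing branch", {
  t_true <- parse_ddi_tree(mini_tree_doc("LT", 3.5, "TRUE_BRANCH"))
  t_false <- parse_ddi_tree(mini_tree_doc("LT", 3.5, "FALSE_BRANCH"))
  expect_equal(evaluate_tree(t_true, list(serum_potassium = NA))$color,
               evaluate_tree(t_true, list(serum_potassium = 3.0))$color)
  expect_equal(evaluate_tree(t_false, list(serum_potassium = NA))$color,
               "GREEN")
  # PRESENT/ABSENT treat MISSING structurally
  t_pres <- parse_ddi_tree(mini_tree_doc("PRESENT", NULL))
  expect_equal(evaluate_tree(t_pres, list(serum_potassium = 4))$color, "RED")
  expect_equal(evaluate_tree(t_pres, list(serum_potassium = NA))$color, "GREEN")
})

test_that("run_algorithm classifies every pair exactly once, sorted", {
  store <- generate_validation_population(1)
  sets <- resolve_concept_sets(bundled_concept_sets(), store)
  tree <- bundled_trees()$citalopram_qt
  pairs <- find_concomitant_pairs(store, sets$citalopram,
                                  sets$qt_prolonging_agents)
  events <- run_algorithm(store, tree, context_config(), sets)
  expect_equal(nrow(events), nrow(pairs))
  expect_false(is.unsorted(order(events$person_id, events$trigger_datetime)))
  expect_true(all(startsWith(events$path, tree$root)))
  expect_true(all(vapply(seq_len(nrow(events)), function(i) {
    parts <- strsplit(events$path[i], ">", fixed = TRUE)[[1]]
    identical(parts[length(parts)], events$leaf_id[i])
  }, logical(1))))
  # no co-exposed persons -> empty event list
  lone <- quick_store(persons = list(list(1L, "1950-01-01", "MALE")))
  expect_equal(nrow(run_algorithm(lone, tree, context_config(),
                                  resolved_sets())), 0L)
})

test_that("per-leaf counts partition the basic pair count (conservation)", {
  trees <- bundled_trees()
  for (seed in c(3, 17)) {
    store <- generate_random(generator_spec(seed = seed, n_persons = 60,
                                            prevalence = c(female = 0.5,
                                                           co_exposure = 0.6,
                                                           context_drug = 0.4)))
    report <- run_all(store, trees)
    p <- report$per_ddi
    expect_equal(p$n_red + p$n_yellow + p$n_green, p$n_basic_concomitant)
    leaf_sums <- tapply(report$leaf_counts$n, report$leaf_counts$ddi_id, sum)
    expect_equal(as.vector(leaf_sums[p$ddi_id]), p$n_basic_concomitant)
  }
})

test_that("identical inputs give byte-identical serialized reports", {
  store <- generate_validation_population(1)
  trees <- bundled_trees()
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_run_report(run_all(store, trees), f1)
  write_run_report(run_all(store, trees), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("flagged trees are risk-monotone and missing-conservative", {
  trees <- bundled_trees()
  flagged <- Filter(function(t) t$monotone_severity, trees)
  expect_gt(length(flagged), 0)
  for (tree in flagged) {
    mono <- check_monotone(tree)
    expect_true(mono$ok, label = paste(tree$ddi_id, "monotone"))
    expect_gt(mono$n, 0)
    miss <- check_missing_conservative(tree)
    expect_true(miss$ok, label = paste(tree$ddi_id, "missing-conservative"))
    expect_gt(miss$n, 0)
  }
})
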
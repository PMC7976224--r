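test_that("the validation population reproduces its fixed census for any seed", {
  for (seed in c(1L, 99L)) {
    store <- generate_validation_population(seed)
    expect_equal(nrow(store$person), 93L)
    expect_equal(nrow(store$measurement), 24L)
    expect_equal(nrow(store$condition_occurrence), 12L)
    expect_equal(nrow(store$drug_exposure), 208L)
    expect_equal(nrow(validate_store(store)), 0L)
  }
})

test_that("the validation population triggers every algorithm and controls stay silent", {
  store <- generate_validation_population(1)
  report <- run_all(store, bundled_trees())
  expect_true(all(report$per_ddi$n_basic_concomitant >= 1L))
  # the duplicate-direction citalopram scenario contributes two alerts
  expect_equal(
    report$per_ddi$n_basic_concomitant[
      report$per_ddi$ddi_id == "citalopram_qt"], 2L)
  # each negative-control pair is non-overlapping: person count with events
  # is strictly greater than alert count for every DDI with one positive
  expect_equal(
    report$per_ddi$n_basic_concomitant[
      report$per_ddi$ddi_id == "warfarin_antidepressant"], 1L)
})

test_that("replica serialization is byte-identical across calls with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_patient_store(generate_validation_population(7), d1)
  write_patient_store(generate_validation_population(7), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("branch coverage reaches every leaf and matches its manifest", {
  trees <- bundled_trees()
  for (tree in trees) {
    store <- generate_branch_coverage(tree, 1)
    manifest <- attr(store, "manifest")
    expect_setequal(manifest$leaf_id, tree_leaves(tree)$leaf_id)
    expect_equal(nrow(validate_store(store)), 0L)
    sets <- resolve_concept_sets(bundled_concept_sets(), store)
    events <- run_algorithm(store, tree, context_config(), sets)
    # one pair per manifest person, leaf-for-leaf agreement
    expect_equal(nrow(events), nrow(manifest))
    expect_identical(events$leaf_id[match(manifest$person_id,
                                          events$person_id)],
                     manifest$leaf_id)
  }
})

test_that("coverage generation handles degenerate and contradictory trees", {
  solo <- parse_ddi_tree(list(
    ddi_id = "solo", object_set = "warfarin", precipitant_set = "aspirin",
    factors = list(), root = "l1",
    nodes = list(l1 = list(kind = "leaf", color = "GREEN"))))
  store <- generate_branch_coverage(solo, 1)
  expect_equal(nrow(attr(store, "manifest")), 1L)

  # a predicate contradiction makes a leaf unreachable -> generation error
  doc <- list(
    ddi_id = "contradiction", object_set = "warfarin",
    precipitant_set = "aspirin",
    factors = list(list(name = "age_years", type = "numeric",
                        extractor = "age", bounds = c(0, 110))),
    root = "n1",
    nodes = list(
      n1 = list(kind = "predicate", factor = "age_years", comparator = "GE",
                threshold = 68, missing_branch = "FALSE_BRANCH",
                true_branch = "n2", false_branch = "leaf_a"),
      n2 = list(kind = "predicate", factor = "age_years", comparator = "LT",
                threshold = 50, missing_branch = "FALSE_BRANCH",
                true_branch = "leaf_b", false_branch = "leaf_c"),
      leaf_a = list(kind = "leaf", color = "GREEN"),
      leaf_b = list(kind = "leaf", color = "RED"),
      leaf_c = list(kind = "leaf", color = "YELLOW")))
  tree <- parse_ddi_tree(doc)
  expect_error(generate_branch_coverage(tree, 1), "leaf_b")
})

test_that("randomized populations honor their spec", {
  # zero persons -> empty clinical tables
  empty <- generate_random(generator_spec(seed = 1, n_persons = 0))
  expect_equal(nrow(empty$person), 0L)
  expect_equal(nrow(empty$drug_exposure), 0L)

  # no deliberate co-exposure -> no alerts for any DDI
  quiet <- generate_random(generator_spec(
    seed = 2, n_persons = 80,
    prevalence = c(female = 0.5, co_exposure = 0, context_drug = 0.3)))
  report <- run_all(quiet, bundled_trees())
  expect_true(all(report$per_ddi$n_basic_concomitant == 0L))

  # determinism: equal specs give structurally equal stores
  a <- generate_random(generator_spec(seed = 5, n_persons = 40))
  b <- generate_random(generator_spec(seed = 5, n_persons = 40))
  expect_identical(unclass(a), unclass(b))

  # every generated store passes the integrity gate
  expect_equal(nrow(validate_store(a)), 0L)
})

test_that("background exposure counts follow the stated Poisson mean", {
  spec <- generator_spec(seed = 31, n_persons = 1000, mean_exposures = 5,
                         mean_measurements = 0, mean_conditions = 0,
                         mean_visits = 0,
                         prevalence = c(female = 0.5, co_exposure = 0,
                                        context_drug = 0))
  store <- generate_random(spec)
  per_person <- tabulate(store$drug_exposure$person_id, nbins = 1000)
  se <- sqrt(5 / 1000)  # Poisson variance = mean
  expect_lt(abs(mean(per_person) - 5), 3 * se)
})
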
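test_that("toy ontologies have the expected geometry and are reproducible", {
  onto <- make_toy_ontology(depth = 2, branching = 3, prefixes = "TOY", seed = 4)
  expect_identical(nrow(onto$graph$terms), 13L) # 1 + 3 + 9
  root <- onto$graph$terms$id[[1]]
  expect_length(relatives(onto$graph, root, "descendants"), 12)
  expect_length(onto$leaves, 9)

  again <- make_toy_ontology(depth = 2, branching = 3, prefixes = "TOY", seed = 4)
  expect_identical(onto$graph$terms, again$graph$terms)

  two <- make_toy_ontology(depth = 1, branching = 2,
                           prefixes = c("AA", "BB"), seed = 1)
  expect_setequal(unique(two$graph$terms$db), c("AA", "BB"))
  # disjoint components: no shared ancestors across prefixes
  expect_identical(nrow(shared_ancestors(two$graph, two$leaves[c(1, 3)])), 0L)
})

test_that("clean cohorts are rectangular, patient-consistent and seeded", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(10, 3, dict, onto$graph, seed = 2)
  expect_identical(nrow(clean), 30L)
  expect_identical(anyDuplicated(clean$curation_id), 0L)
  # time-invariant attribute constant within patient
  per <- tapply(clean$sex, clean$participant_id, dplyr::n_distinct)
  expect_true(all(per == 1))
  # values come from the enum leaves
  sex_labels <- term_label(onto$graph,
                           setdiff(relatives(onto$graph,
                                             "SEXO:0000001", "descendants"),
                                   onto$graph$terms$id[
                                     lengths(onto$graph$children) > 0]))
  expect_true(all(clean$sex %in% sex_labels))
  expect_identical(clean,
                   make_clean_cohort(10, 3, dict, onto$graph, seed = 2))
  # numeric attributes carry units
  expect_true(all(grepl("^[0-9]+ years$", clean$age)))
})

test_that("zero corruption rates leave the cohort untouched", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(8, 2, dict, onto$graph, seed = 3)
  cfg <- corruption_config(typo_rate = 0, abbreviation_rate = 0,
                           binary_encode_rate = 0, dispersal_columns = 1,
                           misplacement_rate = 0, conflict_rate = 0, seed = 3)
  messy <- corrupt_metadata(clean, cfg, onto$graph, dict)
  expect_identical(messy$data, clean)
  expect_identical(nrow(messy$log), 0L)
})

test_that("corruption is reproducible and logged", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(30, 3, dict, onto$graph, seed = 5)
  cfg <- corruption_config(seed = 5)
  m1 <- corrupt_metadata(clean, cfg, onto$graph, dict)
  m2 <- corrupt_metadata(clean, cfg, onto$graph, dict)
  expect_identical(m1$data, m2$data)
  expect_identical(m1$log, m2$log)
})

test_that("conflict injection hits roughly the configured patient fraction", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(100, 3, dict, onto$graph, seed = 6)
  cfg <- corruption_config(typo_rate = 0, abbreviation_rate = 0,
                           binary_encode_rate = 0, dispersal_columns = 1,
                           misplacement_rate = 0, conflict_rate = 0.2, seed = 6)
  messy <- corrupt_metadata(clean, cfg, onto$graph, dict)
  conflicts <- messy$log[messy$log$kind == "conflict", ]
  # per-patient Bernoulli(0.2) over 100 patients: 3 sd binomial band
  expect_gte(nrow(conflicts), 20 - 3 * sqrt(100 * 0.2 * 0.8))
  expect_lte(nrow(conflicts), 20 + 3 * sqrt(100 * 0.2 * 0.8))
  # exactly one flip per affected patient
  pats <- clean$participant_id[conflicts$row]
  expect_identical(anyDuplicated(pats), 0L)
  # every flip differs from truth and is recoverable by consensus
  expect_true(all(messy$data$sex[conflicts$row] != clean$sex[conflicts$row]))
  expect_true(all(conflicts$recoverable))
})

test_that("dispersal partitions the column's non-NA cells", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(20, 2, dict, onto$graph, seed = 7)
  cfg <- corruption_config(typo_rate = 0, abbreviation_rate = 0,
                           binary_encode_rate = 0, dispersal_columns = 3,
                           misplacement_rate = 0, conflict_rate = 0, seed = 7)
  messy <- corrupt_metadata(clean, cfg, onto$graph, dict)
  # the dispersed attribute is replaced by three sparse columns
  expect_false("treatment" %in% names(messy$data))
  cols <- paste0("treatment_v", 1:3)
  expect_true(all(cols %in% names(messy$data)))
  per_cell <- rowSums(!is.na(messy$data[cols]))
  expect_identical(per_cell, as.double(!is.na(clean$treatment)))
  # each non-NA cell appears once, unchanged, in exactly one column
  merged <- dplyr::coalesce(messy$data[[cols[1]]], messy$data[[cols[2]]],
                            messy$data[[cols[3]]])
  expect_identical(merged, clean$treatment)
  expect_setequal(
    messy$plan$original_attribute[messy$plan$curated_attribute == "treatment"],
    cols)
})

test_that("alias corruption is invertible through the oracle maps", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(25, 2, dict, onto$graph, seed = 8)
  cfg <- corruption_config(typo_rate = 0, abbreviation_rate = 0.8,
                           binary_encode_rate = 0, dispersal_columns = 1,
                           misplacement_rate = 0, conflict_rate = 0, seed = 8)
  messy <- corrupt_metadata(clean, cfg, onto$graph, dict)
  expect_false(identical(messy$data$disease, clean$disease))
  mapped <- apply_curation_map(messy$data$disease, messy$maps$disease)
  expect_identical(mapped$curated, clean$disease)
})
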
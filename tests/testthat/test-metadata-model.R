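test_that("curation ids join id fields with ':' in order", {
  tb <- tibble::tibble(study_name = "studyA", participant_id = "p1",
                       sample_id = "s1")
  expect_identical(
    build_curation_id(tb, c("study_name", "participant_id")), "studyA:p1")
  expect_identical(
    build_curation_id(tb, c("study_name", "participant_id", "sample_id")),
    "studyA:p1:s1")
  expect_identical(build_curation_id(tibble::tibble(x = "x"), "x"), "x")
})

test_that("curation ids reject missing components and delimiter collisions", {
  expect_error(
    build_curation_id(tibble::tibble(a = NA_character_, b = "p"), c("a", "b")),
    "missing identifier")
  expect_error(
    build_curation_id(tibble::tibble(a = " ", b = "p"), c("a", "b")),
    "missing identifier")
  expect_error(
    build_curation_id(tibble::tibble(a = "x:y", b = "p"), c("a", "b")),
    "delimiter collision")
  expect_error(
    build_curation_id(tibble::tibble(a = "x"), c("a", "b")), "not in table")
})

test_that("curation ids are injective over distinct id tuples", {
  set.seed(3)
  tb <- tibble::tibble(
    study = sprintf("s%d", sample(1:20, 300, replace = TRUE)),
    pid = sprintf("p%d", sample(1:50, 300, replace = TRUE)),
    sid = sprintf("x%d", seq_len(300)))
  ids <- build_curation_id(tb, c("study", "pid", "sid"))
  expect_identical(anyDuplicated(ids), 0L)
  # and equal tuples give equal ids
  expect_identical(ids, build_curation_id(tb, c("study", "pid", "sid")))
})

test_that("provenance names follow the curated_/original_ schema", {
  nm <- provenance_names("age")
  expect_setequal(nm, c("curated_age", "curated_age_ontology_term_id",
                        "curated_age_source", "original_age_value"))
  expect_true("curated_age_unit" %in% provenance_names("age", "unit"))
  expect_true("original_x_value" %in% provenance_names("x"))
  # disjoint across attribute names
  expect_length(intersect(provenance_names("age"), provenance_names("sex")), 0)
})

test_that("attribute specs enforce their structural invariants", {
  expect_error(attribute_spec("t", "multi", delimiter = NA), "delimiter")
  expect_error(attribute_spec("age", "single", "numeric-with-unit"),
               "unit_attribute")
  expect_error(
    data_dictionary(attribute_spec("a", "single"),
                    attribute_spec("a", "single")),
    "duplicate")
  expect_error(
    data_dictionary(attribute_spec("a", "single", details_partner = "ghost")),
    "does not resolve")
})

test_that("structural validation flags the documented violation kinds", {
  dict <- data_dictionary(
    attribute_spec("sex", "single"),
    attribute_spec("treatment", "multi"),
    version = "t")
  ok <- tibble::tibble(curation_id = c("a:1", "a:2", "a:3"),
                       sex = c("male", "female", NA),
                       treatment = c("x;y", "z", NA))
  expect_identical(nrow(validate_structure(ok, dict)), 0L)

  bad <- tibble::tibble(curation_id = c("a:1", "a:1", "a:3"),
                        sex = c("male;female", "f", NA),
                        mystery = "1",
                        treatment = NA_character_)
  rep <- validate_structure(bad, dict)
  expect_identical(sum(rep$kind == "delimiter-in-single"), 1L)
  expect_identical(sum(rep$kind == "duplicate-curation-id"), 1L)
  expect_identical(sum(rep$kind == "unknown-column"), 1L)

  # required attribute absent
  dict2 <- data_dictionary(attribute_spec("sex", "single", required = TRUE))
  rep2 <- validate_structure(tibble::tibble(curation_id = "a:1"), dict2)
  expect_identical(rep2$kind, "missing-required")
})

test_that("generated cohorts validate cleanly against their dictionary", {
  onto <- sim_ontology()
  dict <- sim_dictionary(onto$graph)
  clean <- make_clean_cohort(5, 2, dict, onto$graph, seed = 1)
  rep <- validate_structure(clean, dict,
                            id_fields = c("study_name", "participant_id",
                                          "sample_id"))
  expect_identical(nrow(rep), 0L)
})

test_that("dictionary rendering splits composites only in curation mode", {
  dict <- data_dictionary(
    attribute_spec("biomarker", "composite"),
    attribute_spec("sex", "single"),
    version = "t")
  members <- list(biomarker = c("CRP", "IL6", "TNF"))
  cur <- render_dictionary(dict, "curation", members)
  rel <- render_dictionary(dict, "release", members)
  expect_identical(sum(cur$name == "biomarker"), 3L)
  expect_identical(sum(rel$name == "biomarker"), 1L)
  expect_error(render_dictionary(dict, "bogus"), "arg")

  no_comp <- data_dictionary(attribute_spec("sex", "single"))
  expect_identical(nrow(render_dictionary(no_comp, "curation")),
                   nrow(render_dictionary(no_comp, "release")))
})

test_that("metadata files round-trip with empty-cell NA encoding", {
  tb <- tibble::tibble(id = c("a", "b"), v = c("x;y", NA))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(tb, p)
  expect_false(any(grepl("NA", readLines(p))))
  back <- read_metadata(p)
  expect_identical(as.data.frame(back), as.data.frame(tb))
  # the literal token NA also parses to missing
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,v\na,NA\nb,", p2)
  expect_true(all(is.na(read_metadata(p2)$v)))
})

test_that("dictionary CSVs round-trip", {
  dict <- sim_dictionary(sim_ontology()$graph)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dictionary(dict, p)
  back <- read_dictionary(p, version = "test")
  expect_identical(back$attributes$name, dict$attributes$name)
  expect_identical(back$attributes$kind, dict$attributes$kind)
  expect_identical(back$attributes$dynamic_enum_nodes,
                   dict$attributes$dynamic_enum_nodes)
})
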
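test_that("clean_value trims, blanks NA-lexicon hits and expands tokens", {
  rules <- cleaning_rules(
    binary_map = tibble::tibble(attribute = "antibiotics", token = "yes",
                                value = "Antibiotic"),
    abbreviations = c("t2d" = "type 2 diabetes"))
  expect_identical(clean_value("", "x", rules), NA_character_)
  expect_identical(clean_value("n/a", "x", rules), NA_character_)
  expect_identical(clean_value("  male ", "x", rules), "male")
  expect_identical(clean_value("yes", "antibiotics", rules), "Antibiotic")
  expect_identical(clean_value("yes", "other", rules), "yes")
  expect_identical(clean_value("T2D", "x", rules), "type 2 diabetes")
  # delimiter aliases normalize, token-wise NA drops
  expect_identical(clean_value("a, b", "x", rules), "a;b")
  expect_identical(clean_value("a;na;b", "x", rules), "a;b")
  expect_identical(clean_value(c(NA, "ok"), "x", rules), c(NA, "ok"))
})

test_that("numeric/unit splitting parses prefixes and flags the rest", {
  res <- split_numeric_unit(c("34 years", "5", "adult", "1.5e2 mg/L", ">89"))
  expect_identical(res$value, c(34, 5, NA, 150, NA))
  expect_identical(res$unit, c("years", NA, NA, "mg/L", NA))
  expect_identical(res$flagged, c(FALSE, FALSE, TRUE, FALSE, TRUE))
})

test_that("curation maps enforce key invariants at load", {
  entry <- function(ov, term = "T", id = NA, db = NA) {
    tibble::tibble(original_value = ov, curated_ontology_term = term,
                   curated_ontology_term_id = id, curated_ontology_term_db = db)
  }
  expect_error(curation_map("x", dplyr::bind_rows(entry("A"), entry("a "))),
               "duplicate")
  expect_error(curation_map("x", entry("a;b")), "delimiter")
  expect_error(curation_map("x", entry("a", id = "NCIT:C1", db = "MONDO")),
               "prefix")
  expect_error(curation_map("x", entry("a")[, 1:3]), "lacks column")
  m <- curation_map("x", entry("ok", id = "NCIT:C1", db = "NCIT"))
  expect_s3_class(m, "curation_map")
})

test_that("the printed multi-drug cell maps to its curated form exactly", {
  res <- apply_curation_map(
    "metformin;sitagliptin;lantus;solostar;novorapid", treatment_map())
  expect_identical(res$curated,
                   "Metformin;Sitagliptin;Insulin Glargine;Insulin Aspart")
  # lantus and solostar are two aliases of one generic drug: one survivor,
  # ids stay aligned with the surviving terms
  expect_identical(res$ids, "NCIT:C61612;NCIT:C73838;NCIT:C29125;NCIT:C48026")
})

test_that("mapping passes through, drops, or collapses as configured", {
  m <- curation_map("x", tibble::tibble(
    original_value = "a", curated_ontology_term = "A",
    curated_ontology_term_id = NA, curated_ontology_term_db = NA))
  pass <- apply_curation_map("a;zzz", m)
  expect_identical(pass$curated, "A;zzz")
  expect_identical(pass$unmapped[[1]], "zzz")
  drop <- apply_curation_map("a;zzz", m, unmapped = "drop")
  expect_identical(drop$curated, "A")

  idmap <- curation_map("x", tibble::tibble(
    original_value = c("A", "B"), curated_ontology_term = c("A", "B"),
    curated_ontology_term_id = NA, curated_ontology_term_db = NA))
  expect_identical(apply_curation_map("A;B", idmap)$curated, "A;B")
  # idempotent when map values are disjoint from keys after normalization
  m2 <- curation_map("x", tibble::tibble(
    original_value = c("met", "sit"),
    curated_ontology_term = c("Metformin", "Sitagliptin"),
    curated_ontology_term_id = NA, curated_ontology_term_db = NA))
  once <- apply_curation_map("met;sit", m2)$curated
  expect_identical(apply_curation_map(once, m2)$curated, once)

  na_res <- apply_curation_map(NA_character_, m)
  expect_true(is.na(na_res$curated) && is.na(na_res$ids))
  expect_length(na_res$unmapped[[1]], 0)
})

test_that("harmonize_attribute pools sources with provenance", {
  tb <- tibble::tibble(
    ancestry_raw = c("white", NA, NA),
    race = c(NA, "asian", NA))
  map <- curation_map("ancestry", tibble::tibble(
    original_value = c("white", "asian"),
    curated_ontology_term = c("European", "Asian"),
    curated_ontology_term_id = c("HANCESTRO:0005", "HANCESTRO:0008"),
    curated_ontology_term_db = "HANCESTRO"))
  res <- harmonize_attribute(tb, "ancestry", c("ancestry_raw", "race"),
                             maps = map)
  expect_identical(res$data$curated_ancestry, c("European", "Asian", NA))
  expect_identical(res$data$curated_ancestry_source,
                   c("ancestry_raw", "race", NA))
  expect_identical(res$data$original_ancestry_value, c("white", "asian", NA))
  expect_identical(res$data$curated_ancestry_ontology_term_id,
                   c("HANCESTRO:0005", "HANCESTRO:0008", NA))
  expect_error(harmonize_attribute(tb, "ancestry", "ghost", maps = map),
               "missing source")
})

test_that("harmonization consolidates to the most specific term", {
  g <- ontology_graph(tibble::tibble(
    id = c("NCIT:C3262", "NCIT:C8509"),
    label = c("Neoplasm", "Primary Neoplasm"),
    parents = list(character(), "NCIT:C3262")))
  tb <- tibble::tibble(sample_class = "neoplasm", sample_type = "primary neoplasm")
  map <- curation_map("sample_type", tibble::tibble(
    original_value = c("neoplasm", "primary neoplasm"),
    curated_ontology_term = c("Neoplasm", "Primary Neoplasm"),
    curated_ontology_term_id = c("NCIT:C3262", "NCIT:C8509"),
    curated_ontology_term_db = "NCIT"))
  res <- harmonize_attribute(tb, "sample_type", c("sample_class", "sample_type"),
                             maps = map, graph = g)
  expect_identical(res$data$curated_sample_type, "Primary Neoplasm")
})

test_that("single-valued conflicts are reported, not dropped", {
  tb <- tibble::tibble(a = "left", b = "right")
  map <- curation_map("side", tibble::tibble(
    original_value = c("left", "right"),
    curated_ontology_term = c("Left", "Right"),
    curated_ontology_term_id = NA, curated_ontology_term_db = NA))
  dict <- data_dictionary(attribute_spec("side", "single"))
  res <- harmonize_attribute(tb, "side", c("a", "b"), maps = map, dict = dict)
  expect_identical(nrow(res$conflicts), 1L)
  expect_identical(res$data$curated_side, "Left;Right")
})

test_that("all-NA sources yield NA curated values and empty provenance", {
  tb <- tibble::tibble(a = NA_character_, b = NA_character_)
  res <- harmonize_attribute(tb, "x", c("a", "b"))
  expect_true(is.na(res$data$curated_x))
  expect_true(is.na(res$data$curated_x_source))
  expect_identical(nrow(res$unmapped), 0L)
})

test_that("unmapped_report counts distinct cleaned tokens, sorted", {
  tb <- tibble::tibble(treatment = c("met", "odd1", "odd1;odd2", "odd1", NA))
  plan <- tibble::tibble(original_attribute = "treatment",
                         curated_attribute = "treatment")
  m <- curation_map("treatment", tibble::tibble(
    original_value = "met", curated_ontology_term = "Metformin",
    curated_ontology_term_id = NA, curated_ontology_term_db = NA))
  rep <- unmapped_report(tb, plan, list(treatment = m))
  expect_identical(rep$value, c("odd1", "odd2"))
  expect_identical(rep$count, c(3L, 1L))

  full <- unmapped_report(tibble::tibble(treatment = c("met", NA)), plan,
                          list(treatment = m))
  expect_identical(nrow(full), 0L)
  na_only <- unmapped_report(tibble::tibble(treatment = NA_character_), plan,
                             list(treatment = m))
  expect_identical(nrow(na_only), 0L)
})
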
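Package: metaharmony
Title: Retrospective Harmonization of Sample-Level Omics Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospectively harmonizing heterogeneous sample-level
    clinical metadata from omics studies into ontology-mapped, provenance-tracked
    tables. Supports curation-map driven value transformation (cleaning,
    numeric/unit splitting, abbreviation and binary-column normalization),
    validation against ontology hierarchies via dynamic enumeration nodes and
    round-trip identifier checks, majority-rule resolution of conflicting
    patient-level annotations, harmonization quality metrics (compression,
    consolidation, correction rate, completeness) and merging-schema tables,
    hierarchy-aware querying that expands terms to synonyms and ontology
    descendants, and wide/long reshaping of multi-valued and composite
    attributes. Includes a synthetic-data generator that emulates messy legacy
    metadata with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    withr
Config/testthat/edition: 3
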
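# metaharmony

Retrospective harmonization of sample-level clinical metadata from omics
studies.

Public repositories of metagenomic and cancer-genomics data carry metadata
whose usefulness is crippled by heterogeneity: the same clinical fact hides
under different attribute names, free-text spellings, brand names,
abbreviations, binary columns, and conflicting per-patient annotations.
metaharmony is a toolkit for curators and data engineers who fix this
*after the fact*: it applies explicit per-attribute curation maps
(`original_value → curated ontology term + CURIE + source db`), tracks
provenance of every transformed cell, validates results against ontology
hierarchies, resolves patient-level conflicts, quantifies the improvement,
and makes the harmonized tables queryable through the hierarchy.

The core operations, in the field's usual notation:

* **ETL transform** — cleaning (NA lexicon, delimiter normalization, binary
  and abbreviation maps), numeric/unit splitting, curation-map application
  with de-duplication and most-specific-term consolidation, provenance
  columns `curated_x`, `curated_x_ontology_term_id`, `curated_x_source`,
  `original_x_value`, and `curation_id = study:participant[:sample]`.
* **Validation** — *dynamic enumerations*: the allowed values of an
  attribute are the ontology descendants of its enum node(s); *round-trip
  validation*: every curated ID is resolved back and compared to its stored
  term; cross-attribute logical constraints; systematic-error detection
  (share of all discordances contributed by one study vs a threshold,
  default 0.5).
* **Conflict resolution** — majority-rule consensus for time-invariant
  attributes: per patient, missing values do not vote, the unique plurality
  value overwrites all rows (missing rows are *inferred*, minority rows
  *corrected*), ties become `NA`.
* **Quality metrics** — compression, consolidation (unique values),
  correction rate, completeness; six-column merging-schema tables,
  one-to-one or many-to-many.
* **Query & reshape** — `tree_filter()` matches queried terms plus synonyms
  plus all ontology descendants; `spread_meta()`/`gather_meta()` convert
  multi-valued and composite attributes between compact and long/wide forms.
* **Synthetic fixtures** — seeded generators for toy ontologies and messy
  cohorts with known ground truth and an exact corruption log, so the whole
  pipeline is testable offline.

## Worked example

A classic curation case: one cell lists five diabetes drugs as entered by
the original study, including two brand names of the same insulin.

```r
library(metaharmony)
tmap <- read_curation_map(system.file("extdata", "maps", "treatment.csv",
                                      package = "metaharmony"))
apply_curation_map("metformin;sitagliptin;lantus;solostar;novorapid", tmap)
#> # A tibble: 1 × 4
#>   curated                                               ids       dbs   unmapped
#>   <chr>                                                 <chr>     <chr> <list>
#> 1 Metformin;Sitagliptin;Insulin Glargine;Insulin Aspart NCIT:C61… NCIT… <chr>
```

`lantus` and `solostar` both map to Insulin Glargine and are collapsed to a
single occurrence; the CURIE string stays aligned with the surviving terms.

Hierarchy-aware querying on the packaged ancestry-ontology snapshot: a
search for `Asian` finds a sample annotated with the *descendant* term
`East Asian`, which exact string matching would miss.

```r
g <- read_obo(system.file("extdata", "hancestro-snippet.obo",
                          package = "metaharmony"))
tb <- tibble::tibble(curation_id = c("a:1", "a:2", "a:3"),
                     ancestry = c("East Asian", "European", "Oceanian"))
tree_filter(tb, "ancestry", "Asian", g)
#> # A tibble: 1 × 2
#>   curation_id ancestry
#>   <chr>       <chr>
#> 1 a:1         East Asian
```

Majority-rule consensus with its audit log:

```r
cc <- tibble::tibble(patient = c("p1", "p1", "p1", "p2", "p2"),
                     sex = c("M", "M", "F", "F", NA))
res <- majority_consensus(cc, "sex", "patient")
tidy(res)
#> # A tibble: 2 × 6
#>   patient_id attribute chosen votes   action    affected_rows
#>   <chr>      <chr>     <chr>  <chr>   <chr>     <chr>
#> 1 p1         sex       M      F:1;M:2 corrected 1;2;3
#> 2 p2         sex       F      F:1     inferred  4;5
```

Patient `p1`'s minority `F` is corrected to the plurality value `M`;
patient `p2`'s missing row is inferred from the one observed value. A
two-way tie would blank the patient to `NA` instead.

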
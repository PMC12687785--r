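---
title: "Harmonizing legacy clinical metadata: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing legacy clinical metadata: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaharmony)
library(tibble)
```

## The problem

Sample-level clinical metadata in public omics repositories is extremely
heterogeneous: the same fact (a sex, an ancestry, a drug exposure) appears
under different attribute names, in different vocabularies, at different
granularities, sometimes as free text, sometimes as a forest of binary
columns, and sometimes in the wrong column altogether. metaharmony implements
a retrospective harmonization model for such data: values are mapped onto
ontology terms through explicit per-attribute curation maps, every transformed
cell keeps its provenance, and the harmonized result can be validated,
queried, and reshaped through the ontology hierarchy.

The package deliberately does **not** automate curation judgment. Curation
maps are inputs; the toolkit makes applying, validating, auditing and using
them mechanical and reproducible.

## Data model

A **metadata table** is a tibble of string cells; empty cells and the literal
token `NA` both read as missing, and missing writes back as an empty field.
Identity comes from ordered ID fields joined by `":"` into a `curation_id`
(e.g. `studyA:p1:s1`). A component containing `":"` is an error rather than a
silently ambiguous identifier, which is why `build_curation_id()` refuses it.

A **data dictionary** declares each curated attribute:

* `kind` — `single` (one value), `multi` (several `";"`-delimited values),
  or `composite` (several named features in one cell);
* `value_class` — ontology-categorical, numeric-with-unit, free text, or
  identifier;
* its dynamic-enumeration nodes, optional `*_details` partner and unit
  attribute.

Composite cells are encoded as `name:value` pairs joined by `";"`
(`"CRP:2.3;IL6:1.1"`). This encoding is this package's declared dialect —
nothing forces it externally, so it is stated here once and used everywhere
(reshaping, validation, query matching on the name part). A literal `";"`
inside a value is unsupported in this version and rejected at map load; no
escaping convention is defined.

Provenance columns follow a fixed naming schema per curated attribute `x`:
`curated_x`, `curated_x_ontology_term_id`, `curated_x_source` (which original
attribute each value came from), `original_x_value` (the raw contributing
cells), plus options such as `curated_x_unit`. `release_rendering()` drops
the `original_*` and `*_source` columns for end users; the provenance
rendering keeps everything. `last_modified` is stamped per row (a single
shared value is the common case); pass a fixed date to `run_pipeline()` for
byte-reproducible output.

## The transform step

`clean_value()` runs before any mapping: trim; blank NA-lexicon hits;
normalize delimiter aliases (`","`, `"|"`) to `";"`; convert binary-column
tokens via a per-attribute binary map (`yes` under `antibiotics` becomes a
descriptive value); expand abbreviations token-wise. The default NA lexicon
is intentionally minimal — `""`, `na`, `n/a`, `not available`,
`not provided`, `-` — because tokens like `Unknown` can be legitimate curated
values (vital status) and must not be blanked silently. It is fully
configurable.

`apply_curation_map()` is deterministic by design: keys are normalized by
trim + case-fold only, with no fuzzy matching in the transform path (fuzzy
suggestion belongs in curator tooling around `unmapped_report()`, not in a
reproducible pipeline). Distinct aliases of one concept — two brand names of
the same drug — collapse to a single occurrence in first-appearance order,
with identifiers kept aligned:

```{r}
tmap <- read_curation_map(system.file("extdata", "maps", "treatment.csv",
                                      package = "metaharmony"))
apply_curation_map("metformin;sitagliptin;lantus;solostar;novorapid", tmap)
```

`harmonize_attribute()` pools several source columns in plan order, cleans
and maps each, de-duplicates, and — when an ontology is loaded — collapses
redundant resolutions of one concept to the most specific term
(`most_specific()`). Values that remain irreconcilable in a single-valued
attribute are *kept*, delimited, and reported as conflicts: silent dropping
would hide exactly the records that need curator or consensus attention.
Numeric cells are split by `split_numeric_unit()` into a leading numeric
literal and a unit; unparseable cells (including censored tokens like
`">89"`) yield `(NA, NA)` and a flag rather than an error, and range-style
tokens are left to an explicit min/max configuration rather than guessed.

## Validation

Three complementary checks:

* **Dynamic enumerations.** An attribute's allowed values are the descendant
  closure of its enum nodes (`allowed_values()`), so the value pool tracks
  the ontology instead of a hand-maintained list. The enum node itself is
  *excluded* by default: the descendants constitute the pool, and including
  the umbrella term is an explicit opt-in (`include_self`). Checking prefers
  CURIEs over labels when an identifier column exists, because identifiers
  are version-stable while labels are display forms. A `*_details` attribute
  is validated against its own, wider enum nodes. Combination cells
  (multi-token ancestry, for example) pass only if every token passes.
* **Round-trip validation** (`roundtrip_validate()`): each curated ID is
  resolved back in the ontology and compared with the stored term
  (case-insensitively, synonyms allowed). This catches label/ID mismatches,
  stale IDs, and obsolete terms — the classic silent killers of curated maps.
* **Cross-attribute constraints** (`check_constraints()`): forbidden
  combinations encoding medical knowledge, e.g. prostate cancer with female
  sex. Missing values never match a rule.

`detect_systematic()` separates systematic from random discordance: when one
study contributes at least a threshold share of all discordant records
(default 0.5 — a majority from one source; there is no canonical value, so
it is configurable), the error is flagged as systematic and should be fixed
at the source rather than voted away sample by sample.

## Conflict resolution

For attributes that cannot legitimately change over time (sex assigned at
birth, genetic ancestry), `majority_consensus()` applies a per-patient
plurality rule: missing values do not vote (otherwise missingness could
force ties, and an all-but-missing patient could never be inferred); the
unique top-count value overwrites all of the patient's rows; ties become
`NA`. "Majority" is implemented as *unique plurality* rather than >50%,
with ties blanked — the strictly-ambiguous case resolves to missing rather
than to an arbitrary winner. The operation refuses non-time-invariant
attributes outright; the pipeline drives it from an explicit whitelist
(default `sex`, `ancestry`). Patients are keyed as participant within study,
so a participant ID reused across studies never pools votes across cohorts.

`reconcile_granularity()` handles values recorded at different resolutions:
ancestor/descendant chains collapse to the most specific term; incomparable
siblings are a real conflict for a single-valued attribute (`NA` + flag),
while a multi-valued attribute keeps all minimal terms.

## Quality metrics

Four per-attribute metrics summarize what harmonization achieved:
**compression** (how many original attributes feed the curated one),
**consolidation** (unique values before vs after), **correction rate**
(share of originally present values changed by curation), and
**completeness** (non-missing fraction). Correction rate compares the
*cleaned* original against the curated value, so whitespace or NA
normalization does not count as a correction — the metric measures semantic
updating. It is only defined for one-to-one pairings and returns `NA` under
many-to-many plans, where "the" original of a curated value is ambiguous.
Unique values are counted per cell by default (the merging schema is a
per-field summary); token-mode counting is exposed for multi-valued
attributes since either convention is defensible, and
`unique_value_reduction()` likewise reports both a per-attribute average and
a pooled figure without privileging one. `build_merging_schema()` emits the
six-column schema table (original/curated field, completeness, unique
values), one row per plan edge, with an optional collapsed rendering when
the plan is a function.

## Hierarchy-aware query and reshaping

`expand_query()` turns each query term into its match-key set: itself, its
synonyms, and the labels/synonyms/CURIEs of all descendants; free text that
does not resolve matches verbatim. `tree_filter()` keeps rows whose tokens
hit the expansion — so a query for a disease finds every annotated subtype —
and is therefore always a superset of exact string filtering. `logic = "all"`
requires every query term's expansion to be hit.

`spread_meta()`/`gather_meta()` convert between compact and long/wide forms.
Spreading a multi-valued attribute duplicates `curation_id` across rows by
design; the spread state is recorded in a table attribute, and structural
validation relaxes the uniqueness invariant for such tables. Gathering
restores a canonical form: multi-valued tokens in first-appearance order
with duplicates removed, composite members in column order. Rows that
disagree on context columns cannot be gathered and raise an error.

## The synthetic-data generator

`make_toy_ontology()`, `make_clean_cohort()` and `corrupt_metadata()` exist
so every pipeline property is testable offline with known ground truth. The
corruption taxonomy mirrors what legacy metadata actually exhibits: typos,
abbreviation/brand-name aliases, binary re-encodings, one attribute
dispersed over sparse columns, cross-column misplacement, and within-patient
conflicts on time-invariant attributes.

Two generator decisions matter for interpreting results:

* **Typos are logged but not mapped.** The oracle curation maps cover every
  ground-truth label and every injected alias, but never the typo strings —
  those stand for the errors only manual correction fixes. Recovery
  experiments therefore measure the map-driven pipeline, not an oracle that
  secretly knows everything.
* **Conflicts are one flip per affected patient, to a sibling value.** With
  at least three samples per patient the true value keeps its plurality, so
  consensus recovery is exact by construction; the conflict rate is the
  per-patient Bernoulli probability of receiving a flip.

The recovery criterion is: after harmonizing with the oracle maps and
applying consensus, every cell matches the clean table **outside the
unrecoverable set**. That set is exactly the `(row, attribute)` pairs the
corruption log marks unrecoverable (typos, misplacements), extended
patient-wide for time-invariant attributes — consensus overwrites whole
patients, so a patient touched by an unrecoverable corruption on such an
attribute is excluded as a unit.

What the generator does **not** emulate: the empirical value distributions,
attribute counts, and missingness structure of real repositories; multi-study
patient overlap; and free-text clinical notes. Passing recovery tests shows
the machinery is correct, not that any particular real corpus harmonizes
losslessly.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of compute per concern: oracle
equivalence on 100 random DAGs of up to 50 nodes, reshaping round-trips on
200 random fixtures, 50 injected corruption detections, recovery on cohorts
of 80–110 patients × 3 samples (≈ 900–1000 compared cells). Determinism:
every generator takes an explicit integer seed; the pipeline writes
byte-identical output under a fixed `last_modified` timestamp; tie-breaks in
consensus are by the tie→NA rule rather than any ordering; duplicate
collapse everywhere keeps first-occurrence order so provenance alignment is
stable under row order.

## Known limitations

* Only `is_a` hierarchy is modeled; no OWL reasoning, no relationship types,
  no live ontology-service lookups. Validation runs against a local ontology
  snapshot, so snapshot drift between curation time and validation time is
  visible as round-trip findings, not resolved automatically.
* Cross-prefix edges are never inferred; multi-ontology graphs are disjoint
  components, and label resolution across prefixes follows a caller-supplied
  priority order (file order by default).
* No probabilistic or source-weighted voting in consensus; a study known to
  be unreliable should be fixed via systematic-error handling, not weights.
* Curation maps are exact after trim + case-fold; misspelled originals stay
  unmapped (by design) and surface in `unmapped_report()`.
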
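#' Recover a corrupted cohort with the map-driven pipeline
#'
#' Runs the full harmonization chain over a corrupted cohort from
#' [corrupt_metadata()]: every curated attribute is rebuilt from its plan
#' sources with the oracle curation maps and cleaning rules, then each
#' time-invariant attribute is resolved by [majority_consensus()] per patient.
#' The result has one plain column per curated attribute (prefix stripped) so
#' it aligns cell-for-cell with the clean ground-truth table.
#'
#' @param bundle The list returned by [corrupt_metadata()].
#' @param dict The [data_dictionary()] used to generate the cohort.
#' @param graph The [ontology_graph()].
#' @param time_invariant Attributes resolved by consensus.
#' @return A tibble with `curation_id` and one column per curated attribute.
#' @export
recover_cohort <- function(bundle, dict, graph,
                           time_invariant = c("sex", "ancestry")) {
  data <- bundle$data
  out <- data[, intersect(c("study_name", "participant_id", "sample_id",
                            "curation_id"), names(data))]
  for (attr in unique(bundle$plan$curated_attribute)) {
    sources <- bundle$plan$original_attribute[
      bundle$plan$curated_attribute == attr]
    res <- harmonize_attribute(data, attr, sources, maps = bundle$maps[[attr]],
                               rules = bundle$rules, dict = dict,
                               graph = graph, unmapped = "pass")
    out[[attr]] <- res$data[[paste0("curated_", attr)]]
  }
  patient <- paste(out$study_name, out$participant_id, sep = ":")
  out$.patient <- patient
  for (attr in intersect(time_invariant, names(out))) {
    out <- majority_consensus(out, attr, ".patient")$data
  }
  out$.patient <- NULL
  out
}

#' Ground-truth recovery rate outside the unrecoverable set
#'
#' Compares a recovered cohort to its clean ground truth cell by cell
#' (multi-valued cells compared as token sets). Cells touched by
#' unrecoverable corruptions are excluded, exactly as the corruption log
#' defines them: every `(row, attribute)` the log marks `recoverable = FALSE`
#' and, for time-invariant attributes (where consensus overwrites whole
#' patients), every row of a patient with any unrecoverable entry on that
#' attribute.
#'
#' @param clean The ground-truth cohort from [make_clean_cohort()].
#' @param recovered Output of [recover_cohort()].
#' @param log The corruption log from [corrupt_metadata()].
#' @param attributes Attribute columns to compare.
#' @param time_invariant Attributes whose exclusions extend patient-wide.
#' @param delimiter Token delimiter.
#' @return A one-row tibble: `cells_compared`, `cells_excluded`,
#'   `cells_matched`, `recovery` (matched / compared).
#' @export
recovery_rate <- function(clean, recovered, log, attributes,
                          time_invariant = c("sex", "ancestry"),
                          delimiter = ";") {
  stopifnot(nrow(clean) == nrow(recovered))
  bad <- log[!log$recoverable, c("row", "attribute"), drop = FALSE]
  compared <- 0L; matched <- 0L; excluded <- 0L
  for (attr in attributes) {
    excl_rows <- bad$row[bad$attribute == attr]
    # an attribute dispersed over several columns logs under the column names
    excl_rows <- union(excl_rows,
                       bad$row[startsWith(bad$attribute, paste0(attr, "_"))])
    if (attr %in% time_invariant && length(excl_rows)) {
      pats <- unique(clean$participant_id[excl_rows])
      excl_rows <- which(clean$participant_id %in% pats)
    }
    a <- canonical_cells(clean[[attr]], delimiter, sort = TRUE)
    b <- canonical_cells(recovered[[attr]], delimiter, sort = TRUE)
    keep <- setdiff(seq_len(nrow(clean)), excl_rows)
    excluded <- excluded + length(excl_rows)
    compared <- compared + length(keep)
    matched <- matched + sum((is.na(a[keep]) & is.na(b[keep])) |
                               (!is.na(a[keep]) & !is.na(b[keep]) &
                                  a[keep] == b[keep]))
  }
  tibble::tibble(cells_compared = compared, cells_excluded = excluded,
                 cells_matched = matched, recovery = matched / compared)
}
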
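#' Majority-rule consensus for time-invariant attributes
#'
#' Attributes that cannot legitimately change over time (sex assigned at
#' birth, genetic ancestry) must agree across all of a patient's samples.
#' Within each patient, missing values do not vote; the value appearing most
#' frequently wins (unique plurality) and overwrites every row of that
#' patient — rows that were missing are *inferred*, rows holding a minority
#' value are *corrected*. When the top counts tie there is no majority and
#' all rows are set to `NA` (*tied-NA*). The operation refuses dynamic
#' clinical attributes (disease stage, treatment status): restrict it to a
#' whitelist of genuinely time-invariant attributes.
#'
#' @param data Metadata tibble.
#' @param attribute Column to resolve.
#' @param patient_col Column identifying the patient (rows sharing it are one
#'   patient's samples).
#' @param time_invariant Assertion that `attribute` is time-invariant; `FALSE`
#'   is an error, not a soft warning.
#' @param id_col Column naming rows in the decision log (default
#'   `"curation_id"` when present, else row numbers).
#' @return An object of class `consensus_result`: a list with `data` (the
#'   table with `attribute` overwritten) and `decisions` (one row per patient:
#'   `patient_id`, `attribute`, `chosen`, `votes` (list), `action` in
#'   `kept`/`inferred`/`corrected`/`tied-NA`, `affected_rows`). Use
#'   [tidy.consensus_result()] / [glance.consensus_result()] for audit views.
#' @export
majority_consensus <- function(data, attribute, patient_col,
                               time_invariant = TRUE, id_col = NULL) {
  if (!isTRUE(time_invariant)) {
    stop("consensus restricted to time-invariant attributes", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  for (col in c(attribute, patient_col)) {
    if (!col %in% names(data)) stop("unknown column: ", col, call. = FALSE)
  }
  id_col <- id_col %||% if ("curation_id" %in% names(data)) "curation_id" else NULL
  row_ids <- if (is.null(id_col)) as.character(seq_len(nrow(data))) else
    as.character(data[[id_col]])

  vals <- data[[attribute]]
  groups <- split(seq_len(nrow(data)), data[[patient_col]])
  decisions <- purrr::imap(groups, function(idx, pid) {
    v <- vals[idx]
    votes <- table(v[!is.na(v)])
    if (!length(votes)) return(NULL) # nothing to decide: all missing
    top <- max(votes)
    winners <- names(votes)[votes == top]
    if (length(winners) > 1L) {
      chosen <- NA_character_
      action <- "tied-NA"
    } else {
      chosen <- winners
      action <- if (length(votes) == 1L && !anyNA(v)) "kept"
      else if (length(votes) == 1L) "inferred"
      else "corrected"
    }
    tibble::tibble(patient_id = pid, attribute = attribute, chosen = chosen,
                   votes = list(stats::setNames(as.integer(votes), names(votes))),
                   action = action, affected_rows = list(row_ids[idx]))
  })
  decisions <- dplyr::bind_rows(c(
    list(tibble::tibble(patient_id = character(), attribute = character(),
                        chosen = character(), votes = list(),
                        action = character(), affected_rows = list())),
    unname(purrr::compact(decisions))))

  for (j in seq_len(nrow(decisions))) {
    idx <- groups[[decisions$patient_id[[j]]]]
    vals[idx] <- decisions$chosen[[j]]
  }
  data[[attribute]] <- vals
  structure(list(data = data, decisions = decisions, attribute = attribute),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> attribute '", x$attribute, "': ",
      nrow(x$decisions), " patient decisions (",
      paste(names(table(x$decisions$action)),
            table(x$decisions$action), sep = "=", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Tidy a consensus result into its decision log
#'
#' One row per patient-level decision, with votes rendered as
#' `value:count` pairs — the audit trail written by the pipeline's TSV log.
#'
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return A tibble `patient_id`, `attribute`, `chosen`, `votes`, `action`,
#'   `affected_rows`.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  dplyr::mutate(
    x$decisions,
    votes = purrr::map_chr(.data$votes, function(v)
      paste(names(v), v, sep = ":", collapse = ";")),
    affected_rows = purrr::map_chr(.data$affected_rows, paste, collapse = ";"))
}

#' @rdname tidy.consensus_result
#' @return For `glance`: a one-row tibble of counts per action plus rows
#'   touched.
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  acts <- c("kept", "inferred", "corrected", "tied-NA")
  counts <- purrr::map_int(acts, function(a) sum(x$decisions$action == a))
  out <- tibble::as_tibble(stats::setNames(as.list(counts),
                                           sub("-", "_", acts)))
  dplyr::mutate(out, n_patients = nrow(x$decisions))
}

#' Reconcile values recorded at different granularities
#'
#' Values forming ancestor/descendant chains in the ontology collapse to the
#' most specific term. Incomparable siblings are a genuine conflict for a
#' single-valued attribute — resolved to `NA` and flagged for the validation
#' report — while a multi-valued attribute simply keeps all minimal terms.
#'
#' @param values Character vector of CURIEs.
#' @param graph An [ontology_graph()].
#' @param multi_valued Is the attribute multi-valued?
#' @return A list with `values` (character vector, possibly length 0 when
#'   resolved to `NA`) and `conflict` (logical).
#' @export
reconcile_granularity <- function(values, graph, multi_valued = FALSE) {
  values <- unique(values[!is.na(values)])
  if (!length(values)) return(list(values = character(), conflict = FALSE))
  minimal <- most_specific(graph, values)
  if (multi_valued || length(minimal) == 1L) {
    list(values = minimal, conflict = FALSE)
  } else {
    list(values = character(), conflict = TRUE)
  }
}
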
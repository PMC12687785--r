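#' Dynamic enumeration definitions
#'
#' A dynamic enum declares that the allowed values of an attribute are the
#' descendants of one or more ontology nodes. The pool updates automatically
#' as the ontology evolves: no hand-maintained value list. By default the
#' enum node itself is not an allowed value (the descendants constitute the
#' pool), and delimited combinations of allowed values are permitted — e.g.
#' an ancestry attribute whose node has eight child categories admits those
#' eight terms and their combinations.
#'
#' @param attribute Attribute name.
#' @param enum_nodes Non-empty character vector of CURIEs.
#' @param include_self Are the enum nodes themselves allowed values?
#' @param allow_combinations May a cell hold several allowed tokens?
#' @return An object of class `dynamic_enum`.
#' @export
dynamic_enum <- function(attribute, enum_nodes, include_self = FALSE,
                         allow_combinations = TRUE) {
  stopifnot(length(enum_nodes) >= 1L)
  structure(list(attribute = attribute, enum_nodes = enum_nodes,
                 include_self = include_self,
                 allow_combinations = allow_combinations),
            class = "dynamic_enum")
}

#' Allowed-value pool of a dynamic enum
#'
#' Union of the descendant closures of the enum nodes, honoring
#' `include_self`.
#'
#' @param graph An [ontology_graph()].
#' @param enum A [dynamic_enum()]; all its nodes must exist in `graph`.
#' @return Tibble `id`, `label` of allowed terms.
#' @export
allowed_values <- function(graph, enum) {
  ids <- unique(unlist(purrr::map(
    enum$enum_nodes, relatives, graph = graph,
    direction = "descendants", include_self = enum$include_self)))
  tibble::tibble(id = ids, label = term_label(graph, ids))
}

new_validation_report <- function() {
  tibble::tibble(curation_id = character(), attribute = character(),
                 token = character(),
                 kind = character(), detail = character())
}

#' Validate curated values against a dynamic enum
#'
#' Every non-missing token is checked for membership of the enum's allowed
#' pool — by CURIE when an aligned identifier column is available (identifiers
#' are version-stable), falling back to case-folded label lookup. Values
#' outside the pool are likely wrong or miscategorized. Combination cells
#' pass only when every token passes and the enum allows combinations.
#'
#' @param values Character vector of curated cells (possibly delimited).
#' @param enum A [dynamic_enum()].
#' @param graph An [ontology_graph()].
#' @param ids Optional aligned character vector of delimited CURIEs.
#' @param curation_ids Optional row identifiers for the report.
#' @param delimiter Token delimiter.
#' @return A validation report tibble (`curation_id`, `attribute`, `token`,
#'   `kind`, `detail`); zero rows when everything is valid.
#' @export
validate_dynamic_enum <- function(values, enum, graph, ids = NULL,
                                  curation_ids = NULL, delimiter = ";") {
  pool <- allowed_values(graph, enum)
  pool_keys <- casefold_trim(pool$label)
  curation_ids <- curation_ids %||% as.character(seq_along(values))
  out <- list()
  flag <- function(i, token, detail) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      curation_id = curation_ids[[i]], attribute = enum$attribute,
      token = token, kind = "enum", detail = detail)
  }
  for (i in seq_along(values)) {
    cell <- values[[i]]
    if (is.na(cell)) next
    toks <- trimws(strsplit(cell, delimiter, fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    tok_ids <- if (!is.null(ids) && !is.na(ids[[i]])) {
      v <- trimws(strsplit(ids[[i]], delimiter, fixed = TRUE)[[1]])
      length(v) <- length(toks)
      ifelse(is.na(v) | !nzchar(v), NA_character_, v)
    } else rep(NA_character_, length(toks))
    if (length(toks) > 1L && !enum$allow_combinations) {
      flag(i, cell, "combination value where combinations are not allowed")
      next
    }
    for (k in seq_along(toks)) {
      ok <- if (!is.na(tok_ids[[k]])) tok_ids[[k]] %in% pool$id else
        casefold_trim(toks[[k]]) %in% pool_keys
      if (!ok) flag(i, toks[[k]], "value outside the dynamic-enum pool")
    }
  }
  dplyr::bind_rows(new_validation_report(), out)
}

#' Cross-attribute logical consistency rules
#'
#' Encodes established medical knowledge as forbidden combinations, e.g. a
#' prostate-cancer diagnosis together with female sex is a logical
#' impossibility that flags an annotation error.
#'
#' @param id Rule identifier.
#' @param if_attribute,if_values When `if_attribute` holds one of
#'   `if_values`...
#' @param then_attribute,forbidden_values ...`then_attribute` must not hold
#'   any of `forbidden_values`.
#' @return A one-row tibble of class `constraint_rule`.
#' @export
constraint_rule <- function(id, if_attribute, if_values,
                            then_attribute, forbidden_values) {
  stopifnot(if_attribute != then_attribute,
            length(if_values) >= 1L, length(forbidden_values) >= 1L)
  out <- tibble::tibble(id = id, if_attribute = if_attribute,
                        if_values = list(if_values),
                        then_attribute = then_attribute,
                        forbidden_values = list(forbidden_values))
  class(out) <- c("constraint_rule", class(out))
  out
}

#' Check logical-consistency constraints on a harmonized table
#'
#' Rows whose `if_attribute` value matches a rule and whose `then_attribute`
#' value is forbidden are flagged. Missing values never match.
#'
#' @param data Harmonized tibble.
#' @param rules A tibble of [constraint_rule()] rows (bind them with
#'   `dplyr::bind_rows()`).
#' @param curation_ids Optional row identifiers (defaults to a `curation_id`
#'   column or row numbers).
#' @return A validation report tibble with `kind = "constraint"`.
#' @export
check_constraints <- function(data, rules, curation_ids = NULL) {
  data <- tibble::as_tibble(data)
  curation_ids <- curation_ids %||% data[["curation_id"]] %||%
    as.character(seq_len(nrow(data)))
  out <- list()
  for (j in seq_len(nrow(rules))) {
    r <- rules[j, ]
    for (col in c(r$if_attribute, r$then_attribute)) {
      if (!col %in% names(data)) stop("unknown attribute: ", col, call. = FALSE)
    }
    a <- casefold_trim(data[[r$if_attribute]])
    b <- casefold_trim(data[[r$then_attribute]])
    hit <- !is.na(a) & !is.na(b) &
      a %in% casefold_trim(r$if_values[[1]]) &
      b %in% casefold_trim(r$forbidden_values[[1]])
    for (i in which(hit)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        curation_id = curation_ids[[i]], attribute = r$then_attribute,
        token = data[[r$then_attribute]][[i]], kind = "constraint",
        detail = paste0("rule ", r$id, ": forbidden with ",
                        r$if_attribute, " = ", data[[r$if_attribute]][[i]]))
    }
  }
  dplyr::bind_rows(new_validation_report(), out)
}

#' Distinguish systematic from random discordances
#'
#' When conflicting annotations concentrate in one study they are likely a
#' systematic recording error to be fixed at the source, not sample-level
#' noise to be resolved by consensus. Each study's share of all discordances
#' is computed; studies at or above the threshold are flagged as candidate
#' systematic errors.
#'
#' @param discordances Tibble with a `study` column (one row per discordant
#'   record).
#' @param threshold Flagging threshold on the share, in (0, 1]; default 0.5
#'   (a majority of all discordances from a single study).
#' @return Tibble `study`, `n`, `share`, `flagged`, sorted by descending
#'   share. Empty input yields an empty result.
#' @export
detect_systematic <- function(discordances, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  discordances <- tibble::as_tibble(discordances)
  if (!nrow(discordances)) {
    return(tibble::tibble(study = character(), n = integer(),
                          share = double(), flagged = logical()))
  }
  dplyr::arrange(
    dplyr::mutate(
      dplyr::count(discordances, .data$study, name = "n"),
      share = .data$n / sum(.data$n),
      flagged = .data$share >= threshold),
    dplyr::desc(.data$share))
}
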
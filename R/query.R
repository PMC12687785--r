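#' Expand query terms with synonyms and ontology descendants
#'
#' Hierarchy-aware search rests on expanding each queried term into the set
#' of strings that should count as a hit: the term itself, all its synonyms,
#' and the labels, synonyms and CURIEs of every descendant. Free text that
#' does not resolve in the ontology contributes itself verbatim (with a
#' warning), so plain string search still works.
#'
#' @param graph An [ontology_graph()].
#' @param terms Character vector of labels, synonyms or CURIEs.
#' @return An object of class `query_expansion`: list of per-term key tibbles
#'   (`key`, `reason` in `seed`/`synonym`/`descendant`), plus a pooled `keys`
#'   tibble.
#' @export
expand_query <- function(graph, terms) {
  stopifnot(length(terms) >= 1L)
  per_term <- purrr::map(terms, function(term) {
    id <- if (has_term(graph, term)) term else {
      cand <- resolve_label(graph, term)
      if (length(cand)) cand[[1]] else NA_character_
    }
    if (is.na(id)) {
      return(tibble::tibble(key = casefold_trim(term), reason = "seed"))
    }
    i <- match(id, graph$terms$id)
    seed_keys <- tibble::tibble(
      key = casefold_trim(c(term, id, graph$terms$label[[i]])), reason = "seed")
    syn_keys <- tibble::tibble(
      key = casefold_trim(graph$terms$synonyms[[i]]), reason = "synonym")
    desc <- relatives(graph, id, "descendants")
    j <- match(desc, graph$terms$id)
    desc_keys <- tibble::tibble(
      key = casefold_trim(c(desc, graph$terms$label[j],
                            unlist(graph$terms$synonyms[j], use.names = FALSE))),
      reason = "descendant")
    keys <- dplyr::bind_rows(seed_keys, syn_keys, desc_keys)
    keys[!duplicated(keys$key), , drop = FALSE]
  })
  unresolved <- terms[purrr::map_lgl(seq_along(terms), function(k)
    !has_term(graph, terms[[k]]) && !length(resolve_label(graph, terms[[k]])))]
  if (length(unresolved)) {
    warning("unresolved query term(s) used verbatim: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  structure(list(seed_terms = terms, per_term = per_term,
                 keys = dplyr::distinct(dplyr::bind_rows(per_term))),
            class = "query_expansion")
}

#' @export
print.query_expansion <- function(x, ...) {
  cat("<query_expansion> ", length(x$seed_terms), " seed term(s) -> ",
      nrow(x$keys), " match keys\n", sep = "")
  invisible(x)
}

cell_match_keys <- function(cell, delimiter) {
  if (is.na(cell)) return(character())
  toks <- trimws(strsplit(cell, delimiter, fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  # composite "name:value" tokens additionally match on their name part; the
  # full token is always kept so CURIE tokens still match whole
  name_part <- sub(":[^:]*$", "", toks)
  casefold_trim(unique(c(toks, name_part)))
}

#' Filter rows by hierarchy-aware term matching
#'
#' The central query verb: a row is kept when its attribute tokens hit the
#' expansion ([expand_query()]) of the query terms — so searching for a
#' disease returns samples annotated with any descendant subtype, synonym or
#' identifier of it, not just exact strings. With `logic = "any"` one hit
#' from any query term suffices; with `logic = "all"` every query term's
#' expansion must be hit by at least one token. Missing cells never match;
#' row order is preserved.
#'
#' @param data Metadata tibble.
#' @param attribute Column to search.
#' @param query Character vector of query terms (labels, synonyms or CURIEs).
#' @param graph An [ontology_graph()].
#' @param logic `"any"` (default) or `"all"`.
#' @param delimiter Token delimiter.
#' @return The filtered tibble.
#' @export
tree_filter <- function(data, attribute, query, graph,
                        logic = c("any", "all"), delimiter = ";") {
  logic <- match.arg(logic)
  data <- tibble::as_tibble(data)
  if (!attribute %in% names(data)) {
    stop("unknown attribute: ", attribute, call. = FALSE)
  }
  exp <- expand_query(graph, query)
  key_sets <- purrr::map(exp$per_term, function(tb) tb$key)
  keep <- purrr::map_lgl(data[[attribute]], function(cell) {
    keys <- cell_match_keys(cell, delimiter)
    if (!length(keys)) return(FALSE)
    hits <- purrr::map_lgl(key_sets, function(ks) any(keys %in% ks))
    if (logic == "any") any(hits) else all(hits)
  })
  data[keep, , drop = FALSE]
}

#' Spread a multi-valued or composite attribute into long/wide form
#'
#' Multi-valued attributes spread into one row per token (all other columns
#' duplicated, token order preserved); composite attributes — cells of
#' `name:value` pairs — spread into one new column per distinct name
#' (`attribute_name`), `NA` where a sample lacks that member. The spread
#' state is recorded in `attr(x, "spread_on")` so structural validation can
#' relax the `curation_id` uniqueness invariant, and so [gather_meta()] can
#' invert the operation.
#'
#' @param data Metadata tibble.
#' @param attribute Attribute column to spread.
#' @param kind `"multi"` or `"composite"`.
#' @param delimiter Token delimiter.
#' @return The reshaped tibble.
#' @export
spread_meta <- function(data, attribute, kind = c("multi", "composite"),
                        delimiter = ";") {
  kind <- match.arg(kind)
  data <- tibble::as_tibble(data)
  if (!attribute %in% names(data)) stop("unknown attribute: ", attribute,
                                        call. = FALSE)
  if (identical(attr(data, "spread_on"), attribute)) return(data)
  if (kind == "multi") {
    out <- tidyr::separate_longer_delim(data, dplyr::all_of(attribute),
                                        delim = delimiter)
    out[[attribute]] <- dplyr::na_if(trimws(out[[attribute]]), "")
  } else {
    cells <- data[[attribute]]
    pairs <- purrr::imap(cells, function(cell, i) {
      if (is.na(cell)) return(NULL)
      toks <- trimws(strsplit(cell, delimiter, fixed = TRUE)[[1]])
      toks <- toks[nzchar(toks)]
      bad <- !grepl(":", toks, fixed = TRUE)
      if (any(bad)) {
        rid <- if ("curation_id" %in% names(data)) data$curation_id[[i]] else
          as.character(i)
        stop("malformed composite token (no ':') in row ", rid, ": ",
             paste(toks[bad], collapse = ", "), call. = FALSE)
      }
      tibble::tibble(.row = i,
                     name = sub(":.*$", "", toks),
                     value = sub("^[^:]*:", "", toks))
    })
    pairs <- dplyr::bind_rows(
      tibble::tibble(.row = integer(), name = character(), value = character()),
      purrr::compact(pairs))
    out <- dplyr::select(data, -dplyr::all_of(attribute))
    for (nm in unique(pairs$name)) {
      col <- rep(NA_character_, nrow(data))
      sel <- pairs[pairs$name == nm, ]
      col[sel$.row] <- sel$value
      out[[paste0(attribute, "_", nm)]] <- col
    }
  }
  attr(out, "spread_on") <- attribute
  attr(out, "spread_kind") <- kind
  out
}

#' Gather a spread table back to its canonical compact form
#'
#' Inverse of [spread_meta()] up to canonical form: multi-valued tokens are
#' reassembled in first-appearance order with duplicates removed; composite
#' members in column order. Rows being merged must agree on every context
#' column — disagreement means the table is not a spread of any single
#' original and is an error.
#'
#' @inheritParams spread_meta
#' @param id_col Column identifying the original rows (default
#'   `"curation_id"`).
#' @return The gathered tibble (spread state attributes removed).
#' @export
gather_meta <- function(data, attribute, kind = c("multi", "composite"),
                        delimiter = ";", id_col = "curation_id") {
  kind <- match.arg(kind)
  data <- tibble::as_tibble(data)
  if (kind == "multi") {
    if (!attribute %in% names(data)) stop("unknown attribute: ", attribute,
                                          call. = FALSE)
    ctx_cols <- setdiff(names(data), attribute)
    key <- if (id_col %in% names(data)) data[[id_col]] else
      do.call(paste, c(data[ctx_cols], sep = "\r"))
    groups <- split(seq_len(nrow(data)), factor(key, levels = unique(key)))
    rows <- purrr::map(groups, function(idx) {
      ctx <- data[idx, ctx_cols, drop = FALSE]
      if (nrow(dplyr::distinct(ctx)) > 1L) {
        stop("non-rectangular gather: context columns disagree within '",
             key[idx[[1]]], "'", call. = FALSE)
      }
      toks <- data[[attribute]][idx]
      toks <- unique(toks[!is.na(toks)])
      row <- ctx[1, , drop = FALSE]
      row[[attribute]] <- if (length(toks)) paste(toks, collapse = delimiter)
      else NA_character_
      row
    })
    out <- dplyr::bind_rows(rows)
    out <- out[, names(data), drop = FALSE]
  } else {
    prefix <- paste0(attribute, "_")
    member_cols <- names(data)[startsWith(names(data), prefix)]
    if (!length(member_cols)) {
      # a composite whose cells were all NA spreads to zero member columns
      if (identical(attr(data, "spread_on"), attribute)) {
        data[[attribute]] <- NA_character_
        attr(data, "spread_on") <- NULL
        attr(data, "spread_kind") <- NULL
        return(data)
      }
      stop("no spread columns found for attribute: ", attribute, call. = FALSE)
    }
    vals <- purrr::map(seq_len(nrow(data)), function(i) {
      present <- !is.na(unlist(data[i, member_cols]))
      if (!any(present)) return(NA_character_)
      nm <- substring(member_cols[present], nchar(prefix) + 1L)
      paste(nm, unlist(data[i, member_cols])[present],
            sep = ":", collapse = delimiter)
    })
    out <- dplyr::select(data, -dplyr::all_of(member_cols))
    out[[attribute]] <- unlist(vals)
  }
  attr(out, "spread_on") <- NULL
  attr(out, "spread_kind") <- NULL
  out
}

#' Canonicalize multi-valued cells for set-wise comparison
#'
#' Removes duplicate tokens keeping first appearance; with `sort = TRUE`
#' sorts tokens so set-equal cells compare equal.
#'
#' @param x Character vector of delimited cells.
#' @param delimiter Token delimiter.
#' @param sort Sort tokens?
#' @return Character vector of canonical cells.
#' @export
canonical_cells <- function(x, delimiter = ";", sort = FALSE) {
  vapply(as.character(x), function(cell) {
    if (is.na(cell)) return(NA_character_)
    toks <- trimws(strsplit(cell, delimiter, fixed = TRUE)[[1]])
    toks <- unique(toks[nzchar(toks)])
    if (sort) toks <- sort(toks)
    if (!length(toks)) NA_character_ else paste(toks, collapse = delimiter)
  }, character(1), USE.NAMES = FALSE)
}
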
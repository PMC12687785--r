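#' In-memory ontology graphs
#'
#' An `ontology_graph` is a directed acyclic graph of CURIE-identified terms
#' (`PREFIX:LOCAL`) with labels, synonyms and `is_a` parent links. It powers
#' dynamic-enumeration validation, specificity reduction of redundant values,
#' and hierarchy-aware query expansion. A graph may hold several ontology
#' prefixes side by side as disjoint components; no cross-prefix edges are
#' ever inferred.
#'
#' @param terms A tibble with columns `id` (CURIE), `label`, and optionally
#'   `parents` (list or pipe-delimited string), `synonyms` (list or
#'   pipe-delimited string), `obsolete` (logical).
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(terms) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("id", "label") %in% names(terms)))
  split_pipe <- function(x) {
    if (is.list(x)) {
      purrr::map(x, function(v) as.character(v[!is.na(v) & nzchar(v)]))
    } else {
      purrr::map(as.character(x), function(v) {
        if (is.na(v) || !nzchar(v)) character() else strsplit(v, "|", fixed = TRUE)[[1]]
      })
    }
  }
  terms$parents <- if ("parents" %in% names(terms)) split_pipe(terms$parents) else
    rep(list(character()), nrow(terms))
  terms$synonyms <- if ("synonyms" %in% names(terms)) split_pipe(terms$synonyms) else
    rep(list(character()), nrow(terms))
  terms$obsolete <- if ("obsolete" %in% names(terms)) {
    isTRUE_vec(terms$obsolete)
  } else {
    rep(FALSE, nrow(terms))
  }

  bad <- !grepl("^[^:[:space:]]+:[^:[:space:]]+$", terms$id)
  if (any(bad)) {
    stop("invalid CURIE id(s): ", paste(utils::head(terms$id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(terms$id)) {
    stop("duplicate term id(s): ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "), call. = FALSE)
  }
  terms$db <- sub(":.*$", "", terms$id)

  parents <- stats::setNames(terms$parents, terms$id)
  known <- terms$id
  dangling <- setdiff(unlist(parents, use.names = FALSE), known)
  # child -> parent edges restricted to known terms; dangling parents flagged
  parents <- purrr::map(parents, intersect, y = known)
  children <- invert_adjacency(parents)

  g <- structure(
    list(terms = terms[, c("id", "label", "db", "obsolete", "parents", "synonyms")],
         parents = parents, children = children, dangling = dangling),
    class = "ontology_graph"
  )
  cyc <- find_cycle(parents)
  if (!is.null(cyc)) {
    stop("cycle detected in ontology: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  g$label_index <- build_label_index(g)
  g
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "1", "yes")
}

invert_adjacency <- function(adj) {
  out <- stats::setNames(rep(list(character()), length(adj)), names(adj))
  for (child in names(adj)) {
    for (p in adj[[child]]) out[[p]] <- c(out[[p]], child)
  }
  out
}

# iterative colored DFS; returns one cycle path or NULL
find_cycle <- function(adj) {
  color <- stats::setNames(rep(0L, length(adj)), names(adj)) # 0 new, 1 open, 2 done
  for (start in names(adj)) {
    if (color[[start]] != 0L) next
    stack <- list(list(node = start, nxt = 1L))
    color[[start]] <- 1L
    path <- start
    while (length(stack)) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]]
      if (top$nxt <= length(nbrs)) {
        stack[[length(stack)]]$nxt <- top$nxt + 1L
        nb <- nbrs[[top$nxt]]
        if (color[[nb]] == 1L) return(c(path[which(path == nb)[1]:length(path)], nb))
        if (color[[nb]] == 0L) {
          color[[nb]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nb, nxt = 1L)
          path <- c(path, nb)
        }
      } else {
        color[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        path <- path[-length(path)]
      }
    }
  }
  NULL
}

build_label_index <- function(g) {
  t <- g$terms
  lab <- tibble::tibble(key = casefold_trim(t$label), id = t$id, match = "label")
  syn <- tibble::tibble(
    key = casefold_trim(unlist(t$synonyms, use.names = FALSE) %||% character()),
    id = rep(t$id, lengths(t$synonyms)),
    match = "synonym"
  )
  dplyr::bind_rows(lab, syn)
}

casefold_trim <- function(x) tolower(trimws(x))

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms (",
      paste(unique(x$terms$db), collapse = ", "), "), ",
      sum(lengths(x$parents)), " is_a edges",
      if (length(x$dangling)) paste0(", ", length(x$dangling), " dangling parent ids"),
      "\n", sep = "")
  invisible(x)
}

has_term <- function(graph, id) id %in% graph$terms$id

term_label <- function(graph, ids) {
  graph$terms$label[match(ids, graph$terms$id)]
}

#' Transitive relatives of an ontology term
#'
#' Walks `is_a` edges from `node` and returns the full transitive closure of
#' descendants or ancestors. Descendant closures are what turn a dynamic
#' enumeration node into its pool of allowed values.
#'
#' @param graph An [ontology_graph()].
#' @param node CURIE of the start term.
#' @param direction `"descendants"` (default) or `"ancestors"`.
#' @param include_self Include `node` itself in the result? Default `FALSE`.
#' @param include_obsolete Include obsolete terms? Default `FALSE`.
#' @return Character vector of CURIEs (unordered set).
#' @export
relatives <- function(graph, node,
                      direction = c("descendants", "ancestors"),
                      include_self = FALSE, include_obsolete = FALSE) {
  direction <- match.arg(direction)
  if (!has_term(graph, node)) stop("term not found: ", node, call. = FALSE)
  adj <- if (direction == "descendants") graph$children else graph$parents
  seen <- character()
  frontier <- node
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out <- if (include_self) union(node, seen) else setdiff(seen, node)
  if (!include_obsolete) {
    obs <- graph$terms$id[graph$terms$obsolete]
    out <- setdiff(out, setdiff(obs, if (include_self) node else character()))
  }
  out
}

#' Resolve free text to candidate ontology terms
#'
#' Matches after trimming and case-folding, first against term labels and then
#' against synonyms; exact label matches rank before synonym matches.
#'
#' @inheritParams relatives
#' @param text A single string to resolve.
#' @param prefixes Optional character vector giving ontology-prefix priority;
#'   candidates are ordered by it (unlisted prefixes keep file order).
#' @return Character vector of candidate CURIEs (empty when nothing matches).
#' @export
resolve_label <- function(graph, text, prefixes = NULL) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  hits <- graph$label_index[graph$label_index$key == casefold_trim(text), , drop = FALSE]
  if (!nrow(hits)) return(character())
  hits <- hits[order(match(hits$match, c("label", "synonym"))), , drop = FALSE]
  if (!is.null(prefixes)) {
    pr <- sub(":.*$", "", hits$id)
    hits <- hits[order(match(pr, prefixes, nomatch = length(prefixes) + 1L),
                       match(hits$match, c("label", "synonym"))), , drop = FALSE]
  }
  unique(hits$id)
}

#' Round-trip validation of curated term/identifier pairs
#'
#' Looks each curated ontology ID back up in the graph and compares the term
#' stored there (label or any synonym, case-insensitively) against the curated
#' term string. This catches swapped labels, stale identifiers, and terms that
#' have gone obsolete since curation.
#'
#' @inheritParams relatives
#' @param entries A tibble (or data frame) with columns `term` and `id`.
#' @return A tibble of mismatches with columns `id`, `term`, `found_label`,
#'   `reason` (`"unknown-id"`, `"label-mismatch"` or `"obsolete"`); zero rows
#'   when all entries are consistent.
#' @export
roundtrip_validate <- function(entries, graph) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("term", "id") %in% names(entries)))
  empty <- tibble::tibble(id = character(), term = character(),
                          found_label = character(), reason = character())
  if (!nrow(entries)) return(empty)
  rows <- purrr::pmap(entries[, c("term", "id")], function(term, id) {
    i <- match(id, graph$terms$id)
    if (is.na(i)) {
      return(tibble::tibble(id = id, term = term, found_label = NA_character_,
                            reason = "unknown-id"))
    }
    lab <- graph$terms$label[[i]]
    if (graph$terms$obsolete[[i]]) {
      return(tibble::tibble(id = id, term = term, found_label = lab,
                            reason = "obsolete"))
    }
    ok <- casefold_trim(term) %in% casefold_trim(c(lab, graph$terms$synonyms[[i]]))
    if (ok) NULL else tibble::tibble(id = id, term = term, found_label = lab,
                                     reason = "label-mismatch")
  })
  dplyr::bind_rows(empty, purrr::compact(rows))
}

#' Reduce a value set to its most specific terms
#'
#' Drops every term that is a strict ancestor of another member of the set,
#' implementing consolidation "to the most specific information" when the same
#' concept was recorded at several resolutions. Unrelated terms are all kept.
#'
#' @inheritParams relatives
#' @param values Character vector of CURIEs, all present in `graph`.
#' @return Character vector: the minimal (most specific) members of `values`,
#'   in first-occurrence order.
#' @export
most_specific <- function(graph, values) {
  values <- unique(values)
  missing <- values[!values %in% graph$terms$id]
  if (length(missing)) stop("term not found: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  if (length(values) <= 1L) return(values)
  is_strict_anc <- vapply(values, function(v) {
    any(vapply(setdiff(values, v), function(w)
      v %in% relatives(graph, w, "ancestors", include_obsolete = TRUE), logical(1)))
  }, logical(1))
  values[!is_strict_anc]
}

#' Shared ancestors of a value set
#'
#' Intersects the ancestor closures (self included) of all `values`. The
#' minimal members of that intersection are the natural candidates for dynamic
#' enumeration nodes: the tightest terms subsuming everything observed.
#'
#' @inheritParams relatives
#' @param values Non-empty character vector of CURIEs present in `graph`.
#' @return A tibble with columns `id` and `minimal` (logical: not an ancestor
#'   of any other shared ancestor). Zero rows when the values sit under
#'   disjoint roots.
#' @export
shared_ancestors <- function(graph, values) {
  stopifnot(length(values) >= 1L)
  closures <- purrr::map(values, relatives, graph = graph,
                         direction = "ancestors", include_self = TRUE)
  shared <- purrr::reduce(closures, intersect)
  if (!length(shared)) {
    return(tibble::tibble(id = character(), minimal = logical()))
  }
  minimal <- most_specific(graph, shared)
  tibble::tibble(id = shared, minimal = shared %in% minimal)
}
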
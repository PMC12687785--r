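#' Cleaning rules for raw metadata values
#'
#' Bundles the lexicons the value cleaner applies before any ontology mapping:
#' tokens meaning "missing", per-attribute interpretations of binary columns
#' (so a `yes` under an `antibiotics` column becomes a descriptive value),
#' delimiter characters to normalize to `";"`, and an abbreviation lexicon
#' expanded token-wise.
#'
#' The default NA lexicon is deliberately small (`""`, `"na"`, `"n/a"`,
#' `"not available"`, `"not provided"`, `"-"`): tokens like `"Unknown"` can be
#' legitimate curated values (e.g. vital status) and must not be blanked
#' by default.
#'
#' @param na_lexicon Character vector of tokens meaning missing (case-folded
#'   on storage).
#' @param binary_map Tibble with columns `attribute`, `token`, `value`: in
#'   column `attribute`, token `token` (case-insensitive) is replaced by
#'   `value`.
#' @param delimiter_aliases Characters normalized to `";"` before token
#'   splitting.
#' @param abbreviations Named character vector mapping abbreviation
#'   (case-insensitive) to its expansion.
#' @return An object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(na_lexicon = c("", "na", "n/a", "not available",
                                          "not provided", "-"),
                           binary_map = NULL,
                           delimiter_aliases = c(",", "|"),
                           abbreviations = character()) {
  binary_map <- if (is.null(binary_map)) {
    tibble::tibble(attribute = character(), token = character(), value = character())
  } else {
    tibble::as_tibble(binary_map)
  }
  stopifnot(all(c("attribute", "token", "value") %in% names(binary_map)))
  structure(list(
    na_lexicon = unique(casefold_trim(na_lexicon)),
    binary_map = dplyr::mutate(binary_map, token = casefold_trim(.data$token)),
    delimiter_aliases = delimiter_aliases,
    abbreviations = stats::setNames(unname(abbreviations),
                                    casefold_trim(names(abbreviations) %||% character()))
  ), class = "cleaning_rules")
}

#' Clean raw metadata values
#'
#' Vectorized cleaning applied before curation-map lookup: trims whitespace,
#' maps empty strings and NA-lexicon hits to `NA`, normalizes delimiter
#' aliases to `";"`, converts binary-column tokens to descriptive values, and
#' expands abbreviations token-wise. Never errors on ordinary text.
#'
#' @param x Character vector of raw cell values (may contain `NA`).
#' @param attribute Name of the source attribute (drives the binary map).
#' @param rules A [cleaning_rules()] object.
#' @return Character vector of cleaned values (`NA` where nothing
#'   interpretable remains).
#' @export
clean_value <- function(x, attribute = "", rules = cleaning_rules()) {
  bm <- rules$binary_map[rules$binary_map$attribute == attribute, , drop = FALSE]
  vapply(as.character(x), function(cell) {
    if (is.na(cell)) return(NA_character_)
    cell <- trimws(cell)
    if (casefold_trim(cell) %in% rules$na_lexicon) return(NA_character_)
    for (al in rules$delimiter_aliases) cell <- gsub(al, ";", cell, fixed = TRUE)
    toks <- trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
    toks <- vapply(toks, function(tok) {
      key <- casefold_trim(tok)
      if (key %in% rules$na_lexicon) return(NA_character_)
      hit <- match(key, bm$token)
      if (!is.na(hit)) return(bm$value[[hit]])
      if (key %in% names(rules$abbreviations)) rules$abbreviations[[key]]
      else tok
    }, character(1), USE.NAMES = FALSE)
    toks <- toks[!is.na(toks)]
    if (!length(toks)) NA_character_ else paste(toks, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Split numeric values from their units
#'
#' Parses a leading numeric literal (integer, decimal or scientific) and
#' returns the remainder as the unit. Cells with no parseable numeric prefix
#' yield `(NA, NA)` and are flagged rather than raising; censored tokens like
#' `">89"` fall in that flagged class unless handled by a range-split
#' configuration upstream.
#'
#' @param x Character vector of raw values (non-`NA`).
#' @return A tibble with columns `raw`, `value` (double), `unit` (character)
#'   and `flagged` (logical: no numeric prefix found).
#' @export
split_numeric_unit <- function(x) {
  x <- as.character(x)
  pat <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?"
  parsed <- purrr::map(x, function(cell) {
    if (is.na(cell)) return(list(NA_real_, NA_character_, TRUE))
    cell <- trimws(cell)
    m <- regexpr(pat, cell)
    if (m < 1L) return(list(NA_real_, NA_character_, TRUE))
    len <- attr(m, "match.length")
    rest <- trimws(substring(cell, len + 1L))
    list(as.numeric(substring(cell, 1L, len)),
         if (nzchar(rest)) rest else NA_character_, FALSE)
  })
  tibble::tibble(
    raw = x,
    value = purrr::map_dbl(parsed, 1L),
    unit = purrr::map_chr(parsed, 2L),
    flagged = purrr::map_lgl(parsed, 3L)
  )
}

#' Curation maps
#'
#' A curation map is the per-attribute source of truth for the transform step:
#' each distinct original value maps to a curated ontology term with its CURIE
#' identifier and source-ontology prefix. Keys are normalized by trimming and
#' case-folding; a key containing the `";"` delimiter is a load-time error
#' (no escaping rule exists for it).
#'
#' @param attribute Attribute the map belongs to.
#' @param entries Tibble with columns `original_value`, `curated_ontology_term`,
#'   `curated_ontology_term_id`, `curated_ontology_term_db` (the last two may
#'   be `NA`).
#' @return An object of class `curation_map`.
#' @export
curation_map <- function(attribute, entries) {
  entries <- tibble::as_tibble(entries)
  need <- c("original_value", "curated_ontology_term",
            "curated_ontology_term_id", "curated_ontology_term_db")
  missing <- setdiff(need, names(entries))
  if (length(missing)) {
    stop("curation map lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  entries <- entries[, need]
  key <- casefold_trim(entries$original_value)
  if (any(!nzchar(key))) stop("empty original_value in curation map", call. = FALSE)
  if (any(grepl(";", key, fixed = TRUE))) {
    stop("original_value contains the ';' delimiter (unsupported): ",
         paste(utils::head(entries$original_value[grepl(";", key, fixed = TRUE)], 3),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(key)) {
    stop("duplicate normalized original_value(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  id_prefix <- sub(":.*$", "", entries$curated_ontology_term_id)
  both <- !is.na(entries$curated_ontology_term_id) &
    !is.na(entries$curated_ontology_term_db)
  if (any(both & id_prefix != entries$curated_ontology_term_db)) {
    stop("ontology id prefix disagrees with db column", call. = FALSE)
  }
  structure(list(attribute = attribute, entries = entries,
                 keys = key), class = "curation_map")
}

#' @rdname curation_map
#' @param path CSV path; the four map columns are required. On read the
#'   attribute name defaults to the file name without extension.
#' @export
read_curation_map <- function(path, attribute = NULL) {
  tb <- readr::read_csv(path, na = c("", "NA"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  curation_map(attribute %||% sub("\\.[^.]*$", "", basename(path)), tb)
}

#' @rdname curation_map
#' @param map A `curation_map` to write.
#' @export
write_curation_map <- function(map, path) {
  readr::write_csv(map$entries, path, na = "", progress = FALSE)
  invisible(path)
}

map_lookup <- function(map, tokens) {
  if (is.null(map)) return(rep(NA_integer_, length(tokens)))
  match(casefold_trim(tokens), map$keys)
}

#' Apply a curation map to delimited cells
#'
#' Each cell is split on the delimiter, every token normalized (trim +
#' case-fold) and looked up in the map; mapped tokens are replaced by their
#' curated terms. Distinct aliases of the same concept (e.g. two brand names
#' of one drug) collapse to a single occurrence, preserving first-occurrence
#' order, with identifier and ontology-prefix strings kept aligned to the
#' surviving terms. Unmapped tokens are reported and either passed through
#' verbatim or dropped to `NA`.
#'
#' @param x Character vector of cells (may contain `NA`).
#' @param map A [curation_map()] (or `NULL` for pure pass-through).
#' @param delimiter Token delimiter, default `";"`.
#' @param unmapped `"pass"` (keep unmapped tokens verbatim, default) or
#'   `"drop"` (remove them).
#' @return A tibble with columns `curated`, `ids`, `dbs` (delimited strings,
#'   `NA`-valued identifier slots rendered as empty tokens) and `unmapped`
#'   (list column of unmapped tokens per cell).
#' @export
apply_curation_map <- function(x, map, delimiter = ";",
                               unmapped = c("pass", "drop")) {
  unmapped <- match.arg(unmapped)
  out <- purrr::map(as.character(x), function(cell) {
    if (is.na(cell)) {
      return(list(curated = NA_character_, ids = NA_character_,
                  dbs = NA_character_, unmapped = character()))
    }
    toks <- trimws(strsplit(cell, delimiter, fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    hit <- map_lookup(map, toks)
    un <- toks[is.na(hit)]
    term <- ifelse(is.na(hit), toks, map$entries$curated_ontology_term[hit])
    id <- ifelse(is.na(hit), NA_character_, map$entries$curated_ontology_term_id[hit])
    db <- ifelse(is.na(hit), NA_character_, map$entries$curated_ontology_term_db[hit])
    if (unmapped == "drop") {
      keep <- !is.na(hit)
      term <- term[keep]; id <- id[keep]; db <- db[keep]
    }
    first <- !duplicated(term)
    term <- term[first]; id <- id[first]; db <- db[first]
    if (!length(term)) {
      return(list(curated = NA_character_, ids = NA_character_,
                  dbs = NA_character_, unmapped = un))
    }
    list(curated = paste(term, collapse = delimiter),
         ids = if (all(is.na(id))) NA_character_ else
           paste(dplyr::coalesce(id, ""), collapse = delimiter),
         dbs = if (all(is.na(db))) NA_character_ else
           paste(dplyr::coalesce(db, ""), collapse = delimiter),
         unmapped = un)
  })
  tibble::tibble(
    curated = purrr::map_chr(out, "curated"),
    ids = purrr::map_chr(out, "ids"),
    dbs = purrr::map_chr(out, "dbs"),
    unmapped = purrr::map(out, "unmapped")
  )
}

#' Harmonize one curated attribute from its source columns
#'
#' The workhorse of the transform step. For every row, each source cell is
#' cleaned ([clean_value()]) and mapped ([apply_curation_map()]); non-missing
#' results from all sources are pooled in plan order and de-duplicated. For
#' ontology-categorical attributes with a loaded graph, redundant terms at
#' different resolutions collapse to the most specific one. Provenance is
#' recorded: `curated_X_source` lists the contributing source attributes and
#' `original_X_value` the raw contributing cells. Rows where a single-valued
#' attribute still holds several irreconcilable values are reported as
#' conflicts — they are kept in the cell (delimited) for downstream
#' resolution, never silently dropped.
#'
#' @param data Metadata tibble.
#' @param attribute Curated attribute name (without the `curated_` prefix).
#' @param sources Ordered character vector of source column names.
#' @param maps A single [curation_map()] shared by all sources, or a named
#'   list keyed by source attribute. Missing maps are an error unless
#'   `unmapped = "pass"`.
#' @param rules A [cleaning_rules()] object.
#' @param dict Optional [data_dictionary()]; supplies kind/value class and the
#'   delimiter for `attribute`.
#' @param graph Optional [ontology_graph()] enabling specificity reduction.
#' @param unmapped `"pass"` or `"drop"` for unmapped tokens.
#' @return A list with `data` (input plus the four provenance columns),
#'   `conflicts` (tibble `row`, `attribute`, `values`) and `unmapped` (tibble
#'   `attribute`, `source`, `value`, `count`).
#' @export
harmonize_attribute <- function(data, attribute, sources, maps = NULL,
                                rules = cleaning_rules(), dict = NULL,
                                graph = NULL, unmapped = c("pass", "drop")) {
  unmapped <- match.arg(unmapped)
  data <- tibble::as_tibble(data)
  missing_src <- setdiff(sources, names(data))
  if (length(missing_src)) {
    stop("missing source column(s): ", paste(missing_src, collapse = ", "),
         call. = FALSE)
  }
  spec <- if (!is.null(dict)) dict_spec(dict, attribute) else NULL
  delim <- if (!is.null(spec)) spec$delimiter[[1]] else ";"
  kind <- if (!is.null(spec)) spec$kind[[1]] else "multi"
  vclass <- if (!is.null(spec)) spec$value_class[[1]] else "ontology-categorical"

  get_map <- function(src) {
    m <- if (inherits(maps, "curation_map")) maps else maps[[src]]
    if (is.null(m) && unmapped == "drop") {
      stop("no curation map for source '", src, "'", call. = FALSE)
    }
    m
  }

  n <- nrow(data)
  curated <- ids <- src_col <- orig_col <- rep(NA_character_, n)
  conflicts <- list()
  unmapped_toks <- list()

  per_source <- purrr::map(sources, function(src) {
    cleaned <- clean_value(data[[src]], src, rules)
    mapped <- apply_curation_map(cleaned, get_map(src), delimiter = delim,
                                 unmapped = unmapped)
    list(src = src, raw = as.character(data[[src]]), mapped = mapped)
  })

  for (r in seq_len(n)) {
    terms <- character(); tids <- character()
    contrib_src <- character(); contrib_raw <- character()
    for (ps in per_source) {
      cur <- ps$mapped$curated[[r]]
      un <- ps$mapped$unmapped[[r]]
      if (length(un)) {
        unmapped_toks[[length(unmapped_toks) + 1L]] <-
          tibble::tibble(attribute = attribute, source = ps$src, value = un)
      }
      if (is.na(cur)) next
      tk <- strsplit(cur, delim, fixed = TRUE)[[1]]
      idk <- if (is.na(ps$mapped$ids[[r]])) rep(NA_character_, length(tk)) else {
        v <- strsplit(ps$mapped$ids[[r]], delim, fixed = TRUE)[[1]]
        length(v) <- length(tk)
        ifelse(is.na(v) | !nzchar(v), NA_character_, v)
      }
      keep <- !tk %in% terms
      terms <- c(terms, tk[keep]); tids <- c(tids, idk[keep])
      contrib_src <- c(contrib_src, ps$src)
      contrib_raw <- c(contrib_raw, ps$raw[[r]])
    }
    if (!length(terms)) next
    if (!is.null(graph) && vclass == "ontology-categorical") {
      known <- !is.na(tids) & tids %in% graph$terms$id
      if (any(known)) {
        keep_ids <- most_specific(graph, tids[known])
        drop <- known & !tids %in% keep_ids
        terms <- terms[!drop]; tids <- tids[!drop]
      }
    }
    if (kind == "single" && length(terms) > 1L) {
      conflicts[[length(conflicts) + 1L]] <-
        tibble::tibble(row = r, attribute = attribute,
                       values = paste(terms, collapse = delim))
    }
    curated[[r]] <- paste(terms, collapse = delim)
    ids[[r]] <- if (all(is.na(tids))) NA_character_ else
      paste(dplyr::coalesce(tids, ""), collapse = delim)
    src_col[[r]] <- paste(contrib_src, collapse = delim)
    orig_col[[r]] <- paste(contrib_raw, collapse = delim)
  }

  data[[paste0("curated_", attribute)]] <- curated
  data[[paste0("curated_", attribute, "_ontology_term_id")]] <- ids
  data[[paste0("curated_", attribute, "_source")]] <- src_col
  data[[paste0("original_", attribute, "_value")]] <- orig_col

  un_tb <- dplyr::bind_rows(
    tibble::tibble(attribute = character(), source = character(), value = character()),
    unmapped_toks)
  un_tb <- dplyr::arrange(
    dplyr::count(un_tb, .data$attribute, .data$source, .data$value, name = "count"),
    dplyr::desc(.data$count))
  list(
    data = data,
    conflicts = dplyr::bind_rows(
      tibble::tibble(row = integer(), attribute = character(), values = character()),
      conflicts),
    unmapped = un_tb
  )
}

#' Curator work queue: distinct unmapped tokens with counts
#'
#' Runs the cleaning step over every plan edge and tabulates the distinct
#' cleaned tokens that have no curation-map entry, sorted by descending
#' occurrence count — the list a curator works through next.
#'
#' @param data Metadata tibble.
#' @param plan Tibble of plan edges with columns `original_attribute`,
#'   `curated_attribute`.
#' @param maps Named list of [curation_map()] objects keyed by curated
#'   attribute (or by source attribute).
#' @param rules A [cleaning_rules()] object.
#' @param delimiter Token delimiter.
#' @return Tibble `attribute`, `source`, `value`, `count`, sorted by
#'   descending count.
#' @export
unmapped_report <- function(data, plan, maps, rules = cleaning_rules(),
                            delimiter = ";") {
  data <- tibble::as_tibble(data)
  rows <- purrr::pmap(plan[, c("original_attribute", "curated_attribute")],
    function(original_attribute, curated_attribute) {
      if (!original_attribute %in% names(data)) {
        stop("plan references absent column: ", original_attribute, call. = FALSE)
      }
      map <- maps[[curated_attribute]] %||% maps[[original_attribute]]
      cleaned <- clean_value(data[[original_attribute]], original_attribute, rules)
      toks <- unlist(strsplit(cleaned[!is.na(cleaned)], delimiter, fixed = TRUE))
      toks <- trimws(toks)
      toks <- toks[nzchar(toks)]
      un <- toks[is.na(map_lookup(map, toks))]
      if (!length(un)) return(NULL)
      tibble::tibble(attribute = curated_attribute, source = original_attribute,
                     value = un)
    })
  tb <- dplyr::bind_rows(
    tibble::tibble(attribute = character(), source = character(), value = character()),
    purrr::compact(rows))
  dplyr::arrange(
    dplyr::count(tb, .data$attribute, .data$source, .data$value, name = "count"),
    dplyr::desc(.data$count))
}
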
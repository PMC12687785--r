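#' Read an ontology from an OBO file
#'
#' Minimal reader for the OBO tag subset the toolkit needs: `[Term]` stanzas
#' with `id`, `name`, `is_a`, `synonym` and `is_obsolete` tags. Relationship
#' types other than `is_a` are ignored; so are header tags and `[Typedef]`
#' stanzas. Cycles are a load-time error.
#'
#' @param path Path to an OBO file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  stanza_end <- which(grepl("^\\[", lines))
  tag_val <- function(block, tag) {
    hit <- grep(paste0("^", tag, ":"), block, value = TRUE)
    trimws(sub(paste0("^", tag, ":"), "", hit))
  }
  terms <- purrr::map(seq_along(starts), function(k) {
    from <- starts[[k]] + 1L
    nxt <- stanza_end[stanza_end > starts[[k]]]
    to <- if (length(nxt)) nxt[[1]] - 1L else length(lines)
    block <- lines[from:to]
    block <- sub("\\s!.*$", "", block) # strip trailing OBO comments
    id <- tag_val(block, "id")
    if (!length(id)) return(NULL)
    nm <- tag_val(block, "name")
    is_a <- sub("\\s.*$", "", tag_val(block, "is_a"))
    syn_raw <- tag_val(block, "synonym")
    syn <- regmatches(syn_raw, regexpr('"[^"]*"', syn_raw))
    syn <- gsub('"', "", syn)
    obs <- tag_val(block, "is_obsolete")
    tibble::tibble(
      id = id[[1]],
      label = if (length(nm)) nm[[1]] else id[[1]],
      parents = list(is_a),
      synonyms = list(syn),
      obsolete = length(obs) > 0 && tolower(obs[[1]]) == "true"
    )
  })
  ontology_graph(dplyr::bind_rows(terms))
}

#' Read an ontology from a flat term table
#'
#' CSV with columns `id`, `label`, `parents` (pipe-delimited CURIEs),
#' `synonyms` (pipe-delimited) and `obsolete`.
#'
#' @param path Path to a CSV file.
#' @return An [ontology_graph()].
#' @export
read_term_table <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  ontology_graph(tb)
}

#' Write an ontology to a flat term table
#'
#' @param graph An [ontology_graph()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_term_table <- function(graph, path) {
  tb <- graph$terms
  out <- tibble::tibble(
    id = tb$id,
    label = tb$label,
    parents = purrr::map_chr(tb$parents, paste, collapse = "|"),
    synonyms = purrr::map_chr(tb$synonyms, paste, collapse = "|"),
    obsolete = tb$obsolete
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
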
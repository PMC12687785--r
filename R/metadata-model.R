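#' Attribute specifications and data dictionaries
#'
#' An `attribute_spec` describes one curated attribute: its structural kind
#' (`single`, `multi`, `composite`), its value class, the delimiter used for
#' multi-token cells, the ontology nodes acting as its dynamic enumeration,
#' and optional links to a `*_details` partner or a unit attribute. A
#' `data_dictionary` is an ordered, uniquely named collection of such specs
#' with a version string.
#'
#' @param name Attribute name (valid identifier).
#' @param kind `"single"`, `"multi"` or `"composite"`.
#' @param value_class One of `"ontology-categorical"`, `"numeric-with-unit"`,
#'   `"free-text"`, `"identifier"`.
#' @param delimiter Single character separating tokens in multi/composite
#'   cells; default `";"`.
#' @param dynamic_enum_nodes Character vector of CURIEs (may be empty).
#' @param details_partner Optional name of a paired `*_details` attribute.
#' @param unit_attribute Optional name of the attribute holding units;
#'   required when `value_class = "numeric-with-unit"`.
#' @param required Must every row carry a value? Default `FALSE`.
#' @return A one-row tibble of class `attribute_spec`.
#' @export
attribute_spec <- function(name,
                           kind = c("single", "multi", "composite"),
                           value_class = c("ontology-categorical",
                                           "numeric-with-unit",
                                           "free-text", "identifier"),
                           delimiter = ";",
                           dynamic_enum_nodes = character(),
                           details_partner = NA_character_,
                           unit_attribute = NA_character_,
                           required = FALSE) {
  kind <- match.arg(kind)
  value_class <- match.arg(value_class)
  stopifnot(is.character(name), length(name) == 1L,
            grepl("^[A-Za-z][A-Za-z0-9_]*$", name))
  if (kind %in% c("multi", "composite") &&
      (is.na(delimiter) || nchar(delimiter) != 1L)) {
    stop("kind '", kind, "' requires a single-character delimiter", call. = FALSE)
  }
  if (value_class == "numeric-with-unit" && is.na(unit_attribute)) {
    stop("numeric-with-unit attributes need a unit_attribute", call. = FALSE)
  }
  out <- tibble::tibble(
    name = name, kind = kind, value_class = value_class,
    delimiter = delimiter,
    dynamic_enum_nodes = list(dynamic_enum_nodes),
    details_partner = details_partner,
    unit_attribute = unit_attribute,
    required = required
  )
  class(out) <- c("attribute_spec", class(out))
  out
}

#' @rdname attribute_spec
#' @param ... `attribute_spec` rows (or a list of them).
#' @param version Dictionary version string.
#' @export
data_dictionary <- function(..., version = "0") {
  specs <- rlang::list2(...)
  if (length(specs) == 1L && is.list(specs[[1]]) && !inherits(specs[[1]], "tbl_df")) {
    specs <- specs[[1]]
  }
  tb <- dplyr::bind_rows(specs)
  if (anyDuplicated(tb$name)) {
    stop("duplicate attribute name(s): ",
         paste(unique(tb$name[duplicated(tb$name)]), collapse = ", "), call. = FALSE)
  }
  for (col in c("details_partner", "unit_attribute")) {
    ref <- tb[[col]]
    bad <- !is.na(ref) & !ref %in% tb$name
    if (any(bad)) {
      stop(col, " does not resolve: ", paste(ref[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(attributes = tb, version = version), class = "data_dictionary")
}

#' @export
print.data_dictionary <- function(x, ...) {
  cat("<data_dictionary> version ", x$version, ", ",
      nrow(x$attributes), " attributes\n", sep = "")
  print(x$attributes[, c("name", "kind", "value_class", "required")])
  invisible(x)
}

dict_spec <- function(dict, name) {
  i <- match(name, dict$attributes$name)
  if (is.na(i)) stop("unknown attribute: ", name, call. = FALSE)
  dict$attributes[i, , drop = FALSE]
}

#' Build per-sample curation identifiers
#'
#' Joins the values of the ID fields with `":"` in their declared order, e.g.
#' `study_name:participant_id` or `study_name:participant_id:sample_id`,
#' yielding one unique identifier per sample. Components may not be missing,
#' empty, or contain `":"` (that would silently corrupt the identifier).
#'
#' @param data A data frame holding the ID fields.
#' @param id_fields Ordered character vector of ID column names.
#' @return Character vector of curation IDs, one per row.
#' @export
build_curation_id <- function(data, id_fields) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(id_fields, names(data))
  if (length(missing_cols)) {
    stop("id field(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  comp <- purrr::map(id_fields, function(f) as.character(data[[f]]))
  for (k in seq_along(comp)) {
    v <- comp[[k]]
    if (any(is.na(v) | !nzchar(trimws(v)))) {
      stop("missing identifier in field '", id_fields[[k]], "'", call. = FALSE)
    }
    if (any(grepl(":", v, fixed = TRUE))) {
      stop("delimiter collision: field '", id_fields[[k]],
           "' contains ':'", call. = FALSE)
    }
  }
  purrr::reduce(comp, function(a, b) paste(a, b, sep = ":"))
}

#' Provenance column names for a curated attribute
#'
#' The provenance naming schema pairs every curated attribute with columns
#' recording its machine-readable identifier, the original attribute the value
#' came from, and the raw original value:
#' `curated_X`, `curated_X_ontology_term_id`, `curated_X_source`,
#' `original_X_value`, plus `curated_X_{option}` for declared options such as
#' a unit.
#'
#' @param attribute Attribute name.
#' @param option Optional suffix (e.g. `"unit"`).
#' @return Character vector of column names.
#' @export
provenance_names <- function(attribute, option = NULL) {
  stopifnot(grepl("^[A-Za-z][A-Za-z0-9_]*$", attribute))
  out <- c(
    paste0("curated_", attribute),
    paste0("curated_", attribute, "_ontology_term_id"),
    paste0("curated_", attribute, "_source"),
    paste0("original_", attribute, "_value")
  )
  if (!is.null(option)) out <- c(out, paste0("curated_", attribute, "_", option))
  out
}

#' Structural validation of a metadata table against a dictionary
#'
#' Flags unknown columns, missing required attributes, delimiter characters
#' inside single-valued cells, curated columns lacking their provenance
#' partners (when the table carries provenance), and duplicated
#' `curation_id`s. Spread (long-format) tables, marked by
#' `attr(x, "spread_on")`, are exempt from the `curation_id` uniqueness check.
#'
#' @param data A data frame (raw or harmonized metadata).
#' @param dict A [data_dictionary()].
#' @param id_fields Optional ID columns always considered known.
#' @return A tibble of violations with columns `kind`, `column`, `detail`;
#'   zero rows when the table is structurally clean.
#' @export
validate_structure <- function(data, dict, id_fields = character()) {
  data <- tibble::as_tibble(data)
  specs <- dict$attributes
  v <- list()
  add <- function(kind, column, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(kind = kind, column = column, detail = detail)
  }

  known <- c(id_fields, "curation_id", "last_modified", specs$name,
             unlist(purrr::map(specs$name, provenance_names)),
             purrr::map2_chr(specs$name, specs$unit_attribute,
                             function(n, u) if (is.na(u)) NA_character_ else
                               paste0("curated_", n, "_", u)))
  known <- known[!is.na(known)]
  spread_on <- attr(data, "spread_on")
  if (!is.null(spread_on)) {
    known <- c(known, names(data)[startsWith(names(data), paste0(spread_on, "_"))])
  }
  for (col in setdiff(names(data), known)) add("unknown-column", col, "not in dictionary")

  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[[i]]
    col <- if (nm %in% names(data)) nm else paste0("curated_", nm)
    if (specs$required[[i]] && !col %in% names(data)) {
      add("missing-required", nm, "required attribute absent")
      next
    }
    if (!col %in% names(data)) next
    if (specs$kind[[i]] == "single") {
      hits <- which(stringr::str_detect(dplyr::coalesce(data[[col]], ""),
                                        stringr::fixed(specs$delimiter[[i]])))
      for (h in hits) add("delimiter-in-single", col, paste0("row ", h))
    }
    if (paste0("curated_", nm) %in% names(data) &&
        !paste0("original_", nm, "_value") %in% names(data) &&
        any(startsWith(names(data), "original_"))) {
      add("missing-provenance", paste0("original_", nm, "_value"),
          "provenance partner absent")
    }
  }

  if ("curation_id" %in% names(data) && is.null(spread_on)) {
    dup <- unique(data$curation_id[duplicated(data$curation_id)])
    for (d in dup) add("duplicate-curation-id", "curation_id", d)
  }
  dplyr::bind_rows(tibble::tibble(kind = character(), column = character(),
                                  detail = character()), v)
}

#' Render a data dictionary for curators or for release
#'
#' The curation rendering splits composite attributes into one row per member
#' (so each member can be edited in detail); the release rendering presents
#' each composite in its grouped, single-row form.
#'
#' @param dict A [data_dictionary()].
#' @param mode `"curation"` or `"release"`.
#' @param composite_members Named list: composite attribute name -> character
#'   vector of member names. Members default to none (composite rendered as a
#'   single row in both modes if unlisted).
#' @return A tibble, one row per rendered attribute.
#' @export
render_dictionary <- function(dict, mode = c("curation", "release"),
                              composite_members = list()) {
  mode <- match.arg(mode)
  tb <- dict$attributes
  rows <- purrr::map(seq_len(nrow(tb)), function(i) {
    row <- tb[i, c("name", "kind", "value_class", "delimiter", "required")]
    members <- composite_members[[row$name]]
    if (mode == "curation" && row$kind == "composite" && length(members)) {
      dplyr::mutate(row[rep(1L, length(members)), ],
                    member = members, .after = "name")
    } else {
      dplyr::mutate(row, member = NA_character_, .after = "name")
    }
  })
  dplyr::bind_rows(rows)
}

#' Read and write metadata tables
#'
#' Metadata tables are CSV or TSV, UTF-8, with a header row; every cell is
#' read as a string. Empty cells and the literal token `"NA"` parse to `NA`;
#' `NA` is written back as an empty field.
#'
#' @param path File path; delimiter inferred from the extension (`.tsv`/`.txt`
#'   = tab, otherwise comma) unless `delim` is given.
#' @param delim Optional field delimiter override.
#' @return A tibble of character columns.
#' @export
read_metadata <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  readr::read_delim(path, delim = delim, na = c("", "NA"),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
}

#' @rdname read_metadata
#' @param data A data frame to write.
#' @export
write_metadata <- function(data, path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  readr::write_delim(data, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' Read or write a data dictionary CSV
#'
#' Columns: `name, kind, value_class, delimiter, dynamic_enum_nodes`
#' (pipe-delimited CURIEs), `details_partner, unit_attribute, required`.
#'
#' @param path CSV path.
#' @param version Version string attached on read.
#' @return [read_dictionary()]: a [data_dictionary()].
#' @export
read_dictionary <- function(path, version = "0") {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  specs <- purrr::pmap(tb, function(name, kind, value_class, delimiter = ";",
                                    dynamic_enum_nodes = NA, details_partner = NA,
                                    unit_attribute = NA, required = NA, ...) {
    attribute_spec(
      name = name, kind = kind, value_class = value_class,
      delimiter = if (is.na(delimiter)) ";" else delimiter,
      dynamic_enum_nodes = if (is.na(dynamic_enum_nodes)) character() else
        strsplit(dynamic_enum_nodes, "|", fixed = TRUE)[[1]],
      details_partner = details_partner,
      unit_attribute = unit_attribute,
      required = !is.na(required) && tolower(required) %in% c("true", "1", "yes")
    )
  })
  data_dictionary(specs, version = version)
}

#' @rdname read_dictionary
#' @param dict A [data_dictionary()] to write.
#' @export
write_dictionary <- function(dict, path) {
  tb <- dict$attributes
  out <- dplyr::mutate(tb,
    dynamic_enum_nodes = purrr::map_chr(.data$dynamic_enum_nodes, paste, collapse = "|"))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
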
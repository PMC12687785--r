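#' Read a cleaning-rules configuration file
#'
#' YAML (or JSON) with keys `na_lexicon`, `delimiter_aliases`,
#' `abbreviations` (map), and `binary_map` (list of
#' `{attribute, token, value}`).
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A [cleaning_rules()] object.
#' @export
read_cleaning_rules <- function(path) {
  cfg <- read_config_file(path)
  defaults <- cleaning_rules()
  bm <- if (length(cfg$binary_map)) {
    dplyr::bind_rows(purrr::map(cfg$binary_map, tibble::as_tibble))
  } else NULL
  cleaning_rules(
    na_lexicon = cfg$na_lexicon %||% defaults$na_lexicon,
    binary_map = bm,
    delimiter_aliases = cfg$delimiter_aliases %||% defaults$delimiter_aliases,
    abbreviations = unlist(cfg$abbreviations) %||% character()
  )
}

read_config_file <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Load and cross-validate all pipeline inputs
#'
#' Reads the metadata table, data dictionary, ontology (OBO or flat term
#' table), per-attribute curation maps, cleaning rules, merge plan, dynamic
#' enums, constraint rules and the consensus whitelist named by a single
#' config file, then validates every cross-reference. Dangling references are
#' reported exhaustively in one aggregated error, not first-only.
#'
#' Config keys: `metadata`, `dictionary`, `ontology`, `maps_dir`, `cleaning`
#' (inline cleaning rules), `plan` (list of
#' `{curated_attribute, original_attributes}`), `enums` (list of
#' `{attribute, nodes, include_self, allow_combinations}`), `constraints`
#' (list of `{id, if_attribute, if_values, then_attribute,
#' forbidden_values}`), `consensus` (attribute whitelist), `id_fields`.
#' Relative paths resolve against the config file's directory.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent list.
#' @param base_dir Directory for resolving relative paths (defaults to the
#'   config file's directory).
#' @return A list of loaded inputs: `data`, `dict`, `graph`, `maps`, `rules`,
#'   `plan`, `enums`, `constraints`, `consensus`, `id_fields`.
#' @export
load_inputs <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    base_dir <- base_dir %||% dirname(config)
    config <- read_config_file(config)
  }
  base_dir <- base_dir %||% "."
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base_dir, p)

  data <- read_metadata(rel(config$metadata))
  dict <- read_dictionary(rel(config$dictionary))
  graph <- local({
    p <- rel(config$ontology)
    if (grepl("\\.obo$", p)) read_obo(p) else read_term_table(p)
  })
  rules <- if (is.list(config$cleaning)) {
    bm <- if (length(config$cleaning$binary_map)) {
      dplyr::bind_rows(purrr::map(config$cleaning$binary_map, tibble::as_tibble))
    } else NULL
    defaults <- cleaning_rules()
    cleaning_rules(
      na_lexicon = config$cleaning$na_lexicon %||% defaults$na_lexicon,
      binary_map = bm,
      delimiter_aliases = config$cleaning$delimiter_aliases %||%
        defaults$delimiter_aliases,
      abbreviations = unlist(config$cleaning$abbreviations) %||% character())
  } else cleaning_rules()

  plan <- dplyr::bind_rows(purrr::map(config$plan, function(e)
    tibble::tibble(original_attribute = unlist(e$original_attributes),
                   curated_attribute = e$curated_attribute)))

  maps <- list()
  if (!is.null(config$maps_dir)) {
    files <- list.files(rel(config$maps_dir), pattern = "\\.csv$",
                        full.names = TRUE)
    maps <- stats::setNames(purrr::map(files, read_curation_map),
                            sub("\\.csv$", "", basename(files)))
  }

  enums <- purrr::map(config$enums, function(e)
    dynamic_enum(e$attribute, unlist(e$nodes),
                 include_self = isTRUE(e$include_self),
                 allow_combinations = !isFALSE(e$allow_combinations)))
  constraints <- dplyr::bind_rows(purrr::map(config$constraints, function(cst)
    constraint_rule(cst$id, cst$if_attribute, unlist(cst$if_values),
                    cst$then_attribute, unlist(cst$forbidden_values))))

  problems <- character()
  bad_plan <- setdiff(unique(plan$curated_attribute), dict$attributes$name)
  if (length(bad_plan)) {
    problems <- c(problems, paste0("plan curated attribute(s) not in dictionary: ",
                                   paste(bad_plan, collapse = ", ")))
  }
  bad_src <- setdiff(unique(plan$original_attribute), names(data))
  if (length(bad_src)) {
    problems <- c(problems, paste0("plan source column(s) not in metadata: ",
                                   paste(bad_src, collapse = ", ")))
  }
  bad_maps <- setdiff(names(maps), c(dict$attributes$name,
                                     unique(plan$original_attribute)))
  if (length(bad_maps)) {
    problems <- c(problems, paste0("curation map(s) for unknown attribute: ",
                                   paste(bad_maps, collapse = ", ")))
  }
  bad_nodes <- unlist(purrr::map(enums, function(e)
    setdiff(e$enum_nodes, graph$terms$id)))
  if (length(bad_nodes)) {
    problems <- c(problems, paste0("dynamic-enum node(s) not in ontology: ",
                                   paste(unique(bad_nodes), collapse = ", ")))
  }
  if (length(problems)) {
    stop("input cross-validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  message(sprintf("loaded %d rows x %d columns, %d ontology terms, %d maps, %d plan edges",
                  nrow(data), ncol(data), nrow(graph$terms), length(maps),
                  nrow(plan)))
  list(data = data, dict = dict, graph = graph, maps = maps, rules = rules,
       plan = plan, enums = enums, constraints = constraints,
       consensus = unlist(config$consensus) %||% character(),
       id_fields = unlist(config$id_fields) %||%
         intersect(c("study_name", "participant_id", "sample_id"), names(data)))
}

#' Render a harmonized table for release
#'
#' The data-provenance rendering carries every `original_*` and
#' `curated_*_source` column; the release rendering presented to end users
#' drops them and the `curated_` prefix is kept so column meaning stays
#' explicit.
#'
#' @param data Harmonized tibble.
#' @return Tibble without provenance columns.
#' @export
release_rendering <- function(data) {
  drop <- grepl("^original_.*_value$", names(data)) |
    grepl("^curated_.*_source$", names(data))
  tibble::as_tibble(data)[, !drop, drop = FALSE]
}

#' Run the harmonization pipeline
#'
#' Executes the requested stages over loaded inputs and writes the artifacts
#' to `out_dir`: the harmonized table in provenance and release renderings,
#' the validation report, the consensus decision log, the per-attribute
#' quality metrics, the merging schema, and a machine-readable run manifest
#' of per-stage counts. Stage dependencies are checked before anything is
#' written: `consensus`, `validate`, `metrics` and `schema` need curated
#' columns, which either the `harmonize` stage or a pre-harmonized input
#' table must provide. Validation findings do not fail the run; hard errors
#' (broken inputs, dependency violations) do.
#'
#' @param inputs A list from [load_inputs()] (or assembled by hand with the
#'   same element names).
#' @param stages Subset of `c("harmonize", "validate", "consensus",
#'   "metrics", "schema")`.
#' @param out_dir Output directory (created if missing).
#' @param timestamp `last_modified` value stamped on harmonized rows; pass a
#'   fixed date for byte-reproducible runs (default today's date).
#' @return Invisibly, a list with `data` (final table), `manifest` (named
#'   counts) and `files` (paths written).
#' @export
run_pipeline <- function(inputs,
                         stages = c("harmonize", "validate", "consensus",
                                    "metrics", "schema"),
                         out_dir = ".",
                         timestamp = format(Sys.Date())) {
  stages <- match.arg(stages, several.ok = TRUE)
  data <- tibble::as_tibble(inputs$data)
  plan <- inputs$plan
  curated_attrs <- unique(plan$curated_attribute)

  needs_curated <- setdiff(stages, "harmonize")
  if (length(needs_curated) && !"harmonize" %in% stages) {
    have <- paste0("curated_", curated_attrs) %in% names(data)
    if (!all(have)) {
      stop("stage dependency violation: ", paste(needs_curated, collapse = ", "),
           " require curated columns; missing ",
           paste(paste0("curated_", curated_attrs[!have]), collapse = ", "),
           call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  files <- character()
  emit <- function(x, name, writer = write_metadata) {
    p <- file.path(out_dir, name)
    writer(x, p)
    files <<- c(files, p)
  }

  conflicts <- NULL
  if ("harmonize" %in% stages) {
    if (!"curation_id" %in% names(data)) {
      data$curation_id <- build_curation_id(data, inputs$id_fields)
    }
    data$last_modified <- timestamp
    all_unmapped <- list()
    all_conflicts <- list()
    for (attr in curated_attrs) {
      sources <- plan$original_attribute[plan$curated_attribute == attr]
      res <- harmonize_attribute(
        data, attr, sources,
        maps = inputs$maps[[attr]] %||% inputs$maps[sources],
        rules = inputs$rules, dict = inputs$dict, graph = inputs$graph)
      data <- res$data
      all_unmapped[[attr]] <- res$unmapped
      all_conflicts[[attr]] <- res$conflicts
    }
    conflicts <- dplyr::bind_rows(all_conflicts)
    manifest$harmonize <- list(rows = nrow(data), attributes = length(curated_attrs),
                               conflicts = nrow(conflicts),
                               unmapped_tokens = nrow(dplyr::bind_rows(all_unmapped)))
    emit(data, "harmonized_provenance.csv")
    emit(release_rendering(data), "harmonized_release.csv")
  }

  if ("consensus" %in% stages) {
    patient_key <- do.call(paste, c(data[utils::head(inputs$id_fields, 2L)],
                                    sep = ":"))
    data$.patient <- patient_key
    logs <- list()
    for (attr in intersect(inputs$consensus, curated_attrs)) {
      res <- majority_consensus(data, paste0("curated_", attr), ".patient")
      data <- res$data
      logs[[attr]] <- tidy(res)
    }
    data$.patient <- NULL
    log_tb <- dplyr::bind_rows(logs)
    manifest$consensus <- as.list(table(log_tb$action))
    emit(log_tb, "consensus_log.tsv",
         function(x, p) readr::write_tsv(x, p, na = "", progress = FALSE))
  }

  if ("validate" %in% stages) {
    reports <- list()
    for (e in inputs$enums) {
      col <- paste0("curated_", e$attribute)
      if (!col %in% names(data)) next
      idc <- paste0(col, "_ontology_term_id")
      reports[[e$attribute]] <- validate_dynamic_enum(
        data[[col]], e, inputs$graph,
        ids = if (idc %in% names(data)) data[[idc]],
        curation_ids = data[["curation_id"]])
    }
    if (nrow(inputs$constraints %||% tibble::tibble())) {
      reports$constraints <- check_constraints(data, inputs$constraints)
    }
    map_entries <- dplyr::bind_rows(purrr::map(inputs$maps, function(m)
      tibble::tibble(term = m$entries$curated_ontology_term,
                     id = m$entries$curated_ontology_term_id)))
    if (nrow(map_entries)) {
      rt <- roundtrip_validate(map_entries[!is.na(map_entries$id), ],
                               inputs$graph)
      reports$roundtrip <- dplyr::mutate(
        tibble::tibble(curation_id = NA_character_, attribute = "curation-map",
                       token = rt$term, kind = "roundtrip", detail = rt$reason))
    }
    report <- dplyr::bind_rows(c(list(new_validation_report()),
                                 unname(reports)))
    manifest$validate <- list(violations = nrow(report))
    emit(report, "validation_report.tsv",
         function(x, p) readr::write_tsv(x, p, na = "", progress = FALSE))
  }

  if ("metrics" %in% stages) {
    metrics <- harmonization_metrics(inputs$data, data, plan)
    manifest$metrics <- list(attributes = nrow(metrics))
    emit(metrics, "metrics.csv",
         function(x, p) readr::write_csv(x, p, na = "", progress = FALSE))
  }

  if ("schema" %in% stages) {
    schema <- build_merging_schema(plan, inputs$data, data)
    manifest$schema <- list(edges = nrow(schema))
    emit(schema, "merging_schema.csv",
         function(x, p) readr::write_csv(x, p, na = "", progress = FALSE))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(out_dir, "run_manifest.json"))
  for (nm in names(manifest)) {
    message(nm, ": ", paste(names(manifest[[nm]]), unlist(manifest[[nm]]),
                            sep = "=", collapse = ", "))
  }
  invisible(list(data = data, manifest = manifest, files = files,
                 conflicts = conflicts))
}
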
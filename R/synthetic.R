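#' Corruption configuration for the synthetic-data generator
#'
#' Rates for the messy-metadata taxonomy the generator emulates: typos,
#' inconsistent terminologies (abbreviations/brand-name aliases), binary
#' re-encodings, values dispersed over several sparse columns, values
#' misplaced into the wrong attribute, and conflicting annotations within a
#' patient.
#'
#' @param typo_rate,abbreviation_rate,binary_encode_rate,misplacement_rate
#'   Per-cell (or per-row) corruption probabilities in \[0, 1\].
#' @param conflict_rate Per-patient probability of one conflicting sample.
#' @param dispersal_columns Number of sparse columns one attribute is
#'   scattered over (1 = no dispersal).
#' @param seed Integer seed; all generators are bit-reproducible under it.
#' @return A list of class `corruption_config`.
#' @export
corruption_config <- function(typo_rate = 0.05, abbreviation_rate = 0.3,
                              binary_encode_rate = 0.1, dispersal_columns = 1L,
                              misplacement_rate = 0.02, conflict_rate = 0.2,
                              seed = 1L) {
  rates <- c(typo_rate, abbreviation_rate, binary_encode_rate,
             misplacement_rate, conflict_rate)
  stopifnot(all(rates >= 0 & rates <= 1), dispersal_columns >= 1L)
  structure(list(typo_rate = typo_rate, abbreviation_rate = abbreviation_rate,
                 binary_encode_rate = binary_encode_rate,
                 dispersal_columns = as.integer(dispersal_columns),
                 misplacement_rate = misplacement_rate,
                 conflict_rate = conflict_rate, seed = as.integer(seed)),
            class = "corruption_config")
}

#' Generate a toy ontology
#'
#' A rooted DAG per prefix: a complete tree of the given depth and branching
#' factor, with a seeded fraction of nodes receiving a synonym and a second
#' parent (so the graph is a genuine DAG, not a tree). Identifiers and labels
#' are deterministic; multiple prefixes yield disjoint components.
#'
#' @param depth Tree depth below the root (>= 1).
#' @param branching Children per internal node (>= 1).
#' @param prefixes Character vector of CURIE prefixes, one root each.
#' @param seed Integer seed.
#' @param synonym_rate,multiparent_rate Fractions of eligible nodes receiving
#'   a synonym / a second parent.
#' @return A list with `graph` (an [ontology_graph()]) and `leaves`
#'   (character vector of leaf CURIEs).
#' @export
make_toy_ontology <- function(depth, branching, prefixes = "TOY", seed = 1L,
                              synonym_rate = 0.2, multiparent_rate = 0.1) {
  stopifnot(depth >= 1L, branching >= 1L)
  set.seed(seed)
  all_terms <- purrr::map(prefixes, function(pre) {
    n_total <- sum(branching^(0:depth))
    ids <- sprintf("%s:%07d", pre, seq_len(n_total))
    labels <- sprintf("%s term %d", tolower(pre), seq_len(n_total))
    parents <- vector("list", n_total)
    level_of <- integer(n_total)
    parents[[1]] <- character()
    offset <- 1L
    prev_level <- 1L
    for (d in seq_len(depth)) {
      n_level <- branching^d
      idx <- offset + seq_len(n_level)
      parent_idx <- offset - prev_level + ((seq_len(n_level) - 1L) %/% branching) + 1L
      for (k in seq_len(n_level)) parents[[idx[k]]] <- ids[[parent_idx[k]]]
      level_of[idx] <- d
      offset <- offset + n_level
      prev_level <- n_level
    }
    # second parents: pick another node one level up (keeps the graph acyclic)
    for (i in seq_len(n_total)) {
      if (level_of[i] >= 2L && stats::runif(1) < multiparent_rate) {
        cands <- setdiff(which(level_of == level_of[i] - 1L),
                         match(parents[[i]], ids))
        if (length(cands)) {
          parents[[i]] <- c(parents[[i]], ids[[sample(cands, 1L)]])
        }
      }
    }
    syn <- purrr::map(seq_len(n_total), function(i) {
      if (stats::runif(1) < synonym_rate) paste0("syn ", labels[[i]]) else character()
    })
    tibble::tibble(id = ids, label = labels, parents = parents, synonyms = syn,
                   obsolete = FALSE)
  })
  terms <- dplyr::bind_rows(all_terms)
  graph <- ontology_graph(terms)
  leaves <- graph$terms$id[lengths(graph$children[graph$terms$id]) == 0L]
  list(graph = graph, leaves = leaves)
}

#' Generate a clean metadata cohort with known ground truth
#'
#' Draws a tidy sample-level table: `n_patients` patients with
#' `samples_per_patient` samples each, identifier columns
#' (`study_name`, `participant_id`, `sample_id`, `curation_id`), and one
#' column per dictionary attribute. Ontology-categorical values are drawn
#' uniformly from the leaf descendants of the attribute's dynamic-enum nodes
#' (labels, not CURIEs — as raw metadata would record them); multi-valued
#' attributes get one to three tokens; numeric attributes get
#' `"value unit"` strings. Attributes listed in `time_invariant` are constant
#' within a patient. The clean table *is* the ground truth for recovery
#' experiments.
#'
#' @param n_patients,samples_per_patient Cohort dimensions.
#' @param dict A [data_dictionary()].
#' @param graph An [ontology_graph()] resolving the enum nodes.
#' @param seed Integer seed.
#' @param time_invariant Attribute names constant within patient.
#' @param n_studies Patients are split evenly over this many studies.
#' @return A tibble of `n_patients * samples_per_patient` rows.
#' @export
make_clean_cohort <- function(n_patients, samples_per_patient, dict, graph,
                              seed = 1L, time_invariant = c("sex", "ancestry"),
                              n_studies = 1L) {
  set.seed(seed)
  specs <- dict$attributes
  n <- n_patients * samples_per_patient
  study <- sprintf("study%02d", ((seq_len(n_patients) - 1L) %% n_studies) + 1L)
  tb <- tibble::tibble(
    study_name = rep(study, each = samples_per_patient),
    participant_id = rep(sprintf("p%04d", seq_len(n_patients)),
                         each = samples_per_patient),
    sample_id = sprintf("s%05d", seq_len(n))
  )
  tb$curation_id <- build_curation_id(tb, c("study_name", "participant_id",
                                            "sample_id"))
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[[i]]
    if (specs$value_class[[i]] == "ontology-categorical") {
      nodes <- specs$dynamic_enum_nodes[[i]]
      pool <- unique(unlist(purrr::map(nodes, relatives, graph = graph,
                                       direction = "descendants")))
      pool <- pool[lengths(graph$children[pool]) == 0L]
      if (!length(pool)) stop("empty allowed set for attribute: ", nm,
                              call. = FALSE)
      labels <- term_label(graph, pool)
      if (nm %in% time_invariant) {
        per_patient <- sample(labels, n_patients, replace = TRUE)
        tb[[nm]] <- rep(per_patient, each = samples_per_patient)
      } else if (specs$kind[[i]] == "multi") {
        tb[[nm]] <- vapply(seq_len(n), function(.)
          paste(sample(labels, sample(1:3, 1L)), collapse = ";"), character(1))
      } else {
        tb[[nm]] <- sample(labels, n, replace = TRUE)
      }
    } else if (specs$value_class[[i]] == "numeric-with-unit") {
      unit <- if (nm == "age") "years" else "units"
      lo <- if (nm == "age") 18L else 1L
      hi <- if (nm == "age") 90L else 100L
      val <- sample(lo:hi, n_patients, replace = TRUE)
      tb[[nm]] <- paste(rep(val, each = samples_per_patient), unit)
    } else if (specs$value_class[[i]] == "free-text") {
      tb[[nm]] <- sprintf("note %d", sample.int(5L, n, replace = TRUE))
    }
  }
  tb
}

# deterministic abbreviation-style alias of a label ("european ancestry"
# -> "eurpnan..."-like consonant skeleton), unique within a label set
make_alias <- function(labels) {
  base <- vapply(labels, function(l) {
    s <- tolower(gsub("[^a-z ]", "", tolower(l)))
    words <- strsplit(s, " +")[[1]]
    ab <- paste(vapply(words, function(w) {
      core <- gsub("(?<=.)[aeiou]", "", w, perl = TRUE)
      substring(core, 1L, 4L)
    }, character(1)), collapse = "_")
    if (casefold_trim(ab) == casefold_trim(l)) paste0(ab, "_x") else ab
  }, character(1), USE.NAMES = FALSE)
  make.unique(base, sep = "")
}

inject_typo <- function(x, forbidden = character()) {
  out <- if (nchar(x) >= 3L) {
    p <- sample(seq_len(nchar(x) - 1L), 1L)
    paste0(substring(x, 1, p - 1L),
           substring(x, p + 1L, p + 1L), substring(x, p, p),
           substring(x, p + 2L))
  } else paste0(x, "x")
  while (casefold_trim(out) %in% forbidden || casefold_trim(out) == casefold_trim(x)) {
    out <- paste0(out, "q")
  }
  out
}

#' Corrupt a clean cohort into messy legacy metadata
#'
#' Applies, at the configured seeded rates, the corruption taxonomy observed
#' in real legacy metadata: alias substitution (abbreviations / brand names),
#' character-level typos, binary re-encoding (a value moves into a yes/no
#' column named after it), dispersal of one attribute across several sparse
#' columns, cross-column misplacement, and within-patient conflicting values
#' for time-invariant attributes (exactly one flipped sample per affected
#' patient, to a sibling value, so plurality survives at >= 3
#' samples/patient).
#'
#' Alongside the messy table the generator emits exactly what an oracle
#' curator would produce: per-attribute curation maps covering every
#' ground-truth label and every injected alias (typos are deliberately *not*
#' mapped — they stand for errors only manual correction fixes), cleaning
#' rules carrying the induced binary map, the merge-plan edges linking messy
#' source columns to curated attributes, and a corruption log whose
#' `recoverable` flag defines exactly which cells a map+consensus pipeline
#' can restore.
#'
#' @param clean A cohort from [make_clean_cohort()].
#' @param config A [corruption_config()].
#' @param graph The [ontology_graph()] the cohort was drawn from.
#' @param dict The [data_dictionary()].
#' @param time_invariant Attributes eligible for conflict injection.
#' @return A list: `data` (messy tibble), `maps` (named list of
#'   [curation_map()] per curated attribute), `rules` ([cleaning_rules()]),
#'   `plan` (tibble `original_attribute`, `curated_attribute`), `log`
#'   (tibble `row`, `attribute`, `kind`, `recoverable`).
#' @export
corrupt_metadata <- function(clean, config, graph, dict,
                             time_invariant = c("sex", "ancestry")) {
  set.seed(config$seed)
  specs <- dict$attributes
  cat_attrs <- specs$name[specs$value_class == "ontology-categorical" &
                            specs$name %in% names(clean)]
  messy <- tibble::as_tibble(clean)
  log <- list()
  note <- function(row, attribute, kind, recoverable) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      row = row, attribute = attribute, kind = kind, recoverable = recoverable)
  }

  # oracle maps: identity entries for all ground-truth labels, plus aliases
  maps <- list()
  alias_of <- list()
  for (nm in cat_attrs) {
    pool <- unique(unlist(purrr::map(
      specs$dynamic_enum_nodes[[match(nm, specs$name)]],
      relatives, graph = graph, direction = "descendants")))
    pool <- pool[lengths(graph$children[pool]) == 0L]
    labels <- term_label(graph, pool)
    aliases <- make_alias(labels)
    alias_of[[nm]] <- stats::setNames(aliases, labels)
    maps[[nm]] <- curation_map(nm, tibble::tibble(
      original_value = c(labels, aliases),
      curated_ontology_term = c(labels, labels),
      curated_ontology_term_id = c(pool, pool),
      curated_ontology_term_db = sub(":.*$", "", c(pool, pool))))
  }

  plan <- tibble::tibble(original_attribute = cat_attrs,
                         curated_attribute = cat_attrs)
  binary_rows <- list()

  # per-cell corruptions on categorical attributes
  for (nm in cat_attrs) {
    keys <- casefold_trim(maps[[nm]]$entries$original_value)
    spec_i <- match(nm, specs$name)
    delim <- specs$delimiter[[spec_i]]
    for (r in seq_len(nrow(messy))) {
      cell <- messy[[nm]][[r]]
      if (is.na(cell)) next
      toks <- strsplit(cell, delim, fixed = TRUE)[[1]]
      changed <- FALSE
      for (k in seq_along(toks)) {
        u <- stats::runif(1)
        if (u < config$abbreviation_rate) {
          al <- alias_of[[nm]][[toks[[k]]]]
          if (!is.null(al)) { toks[[k]] <- al; changed <- TRUE }
        } else if (u < config$abbreviation_rate + config$typo_rate) {
          toks[[k]] <- inject_typo(toks[[k]], forbidden = keys)
          changed <- TRUE
          note(r, nm, "typo", FALSE)
        }
      }
      if (changed) messy[[nm]][[r]] <- paste(toks, collapse = delim)
    }
  }

  # binary re-encoding: single-valued cells move into a yes/no column named
  # after the value; the induced (column, yes) -> value map is emitted
  bin_attr <- cat_attrs[specs$kind[match(cat_attrs, specs$name)] == "single"]
  if (length(bin_attr) && config$binary_encode_rate > 0) {
    nm <- bin_attr[[1]]
    for (r in seq_len(nrow(messy))) {
      cell <- messy[[nm]][[r]]
      if (is.na(cell) || grepl(";", cell, fixed = TRUE)) next
      if (stats::runif(1) >= config$binary_encode_rate) next
      col <- paste0(nm, "_", gsub("[^a-z0-9]+", "_", tolower(cell)))
      if (!col %in% names(messy)) {
        messy[[col]] <- NA_character_
        binary_rows[[length(binary_rows) + 1L]] <-
          tibble::tibble(attribute = col, token = "yes", value = cell)
        plan <- dplyr::bind_rows(plan, tibble::tibble(
          original_attribute = col, curated_attribute = nm))
      } else if (!any(binary_rows_value(binary_rows, col) == cell)) {
        next # column name collision with a different value: skip this cell
      }
      messy[[col]][[r]] <- "yes"
      messy[[nm]][[r]] <- NA_character_
    }
  }

  # dispersal: scatter the last categorical attribute over sparse columns
  if (config$dispersal_columns > 1L && length(cat_attrs)) {
    nm <- cat_attrs[[length(cat_attrs)]]
    k <- config$dispersal_columns
    cols <- paste0(nm, "_v", seq_len(k))
    assign_to <- sample.int(k, nrow(messy), replace = TRUE)
    for (j in seq_len(k)) {
      v <- rep(NA_character_, nrow(messy))
      sel <- assign_to == j & !is.na(messy[[nm]])
      v[sel] <- messy[[nm]][sel]
      messy[[cols[[j]]]] <- v
    }
    messy[[nm]] <- NULL
    plan <- plan[plan$original_attribute != nm, ]
    plan <- dplyr::bind_rows(plan, tibble::tibble(
      original_attribute = cols, curated_attribute = nm))
  }

  # misplacement: a value lands in another categorical attribute's column
  live_cat <- intersect(cat_attrs, names(messy))
  if (length(live_cat) >= 2L && config$misplacement_rate > 0) {
    for (r in seq_len(nrow(messy))) {
      if (stats::runif(1) >= config$misplacement_rate) next
      from <- sample(live_cat, 1L)
      to <- sample(setdiff(live_cat, from), 1L)
      if (is.na(messy[[from]][[r]]) || !is.na(messy[[to]][[r]])) next
      messy[[to]][[r]] <- messy[[from]][[r]]
      messy[[from]][[r]] <- NA_character_
      note(r, from, "misplacement-lost", FALSE)
      note(r, to, "misplacement-gained", FALSE)
    }
  }

  # conflicts: flip one sample per affected patient to a sibling value
  ti <- intersect(time_invariant, intersect(cat_attrs, names(messy)))
  if (length(ti) && config$conflict_rate > 0) {
    nm <- ti[[1]]
    pool_labels <- unique(maps[[nm]]$entries$curated_ontology_term)
    patients <- split(seq_len(nrow(messy)), clean$participant_id)
    for (idx in patients) {
      if (stats::runif(1) >= config$conflict_rate) next
      r <- idx[[sample.int(length(idx), 1L)]]
      cur <- clean[[nm]][[r]]
      sibs <- setdiff(pool_labels, cur)
      if (!length(sibs) || is.na(messy[[nm]][[r]])) next
      messy[[nm]][[r]] <- sample(sibs, 1L)
      note(r, nm, "conflict", TRUE)
    }
  }

  rules <- cleaning_rules(binary_map = dplyr::bind_rows(
    tibble::tibble(attribute = character(), token = character(),
                   value = character()), binary_rows))
  list(
    data = messy, maps = maps, rules = rules, plan = plan,
    log = dplyr::bind_rows(
      tibble::tibble(row = integer(), attribute = character(),
                     kind = character(), recoverable = logical()), log)
  )
}

binary_rows_value <- function(binary_rows, col) {
  hits <- purrr::keep(binary_rows, function(b) b$attribute == col)
  purrr::map_chr(hits, "value")
}
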
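# Independent brute-force oracles and shared fixtures.
# The oracles work straight off the raw parent lists of the term table and
# never call the package's traversal code.

oracle_parents <- function(graph) {
  stats::setNames(graph$terms$parents, graph$terms$id)
}

oracle_children <- function(graph) {
  par <- oracle_parents(graph)
  out <- stats::setNames(rep(list(character()), length(par)), names(par))
  for (ch in names(par)) for (p in par[[ch]]) out[[p]] <- c(out[[p]], ch)
  out
}

# plain recursive transitive closure
oracle_relatives <- function(graph, node, direction = "descendants",
                             include_self = FALSE) {
  adj <- if (direction == "descendants") oracle_children(graph) else
    oracle_parents(graph)
  walk <- function(x) {
    kids <- adj[[x]]
    unique(c(kids, unlist(lapply(kids, walk))))
  }
  res <- walk(node)
  if (include_self) unique(c(node, res)) else setdiff(res, node)
}

oracle_allowed <- function(graph, nodes, include_self = FALSE) {
  unique(unlist(lapply(nodes, oracle_relatives, graph = graph,
                       direction = "descendants",
                       include_self = include_self)))
}

# random DAG: node i > 1 draws 1-2 parents among nodes 1..i-1
random_dag <- function(n, seed, synonym_rate = 0.3) {
  set.seed(seed)
  ids <- sprintf("RD:%04d", seq_len(n))
  parents <- c(list(character()), lapply(2:n, function(i) {
    k <- sample(1:min(2L, i - 1L), 1L)
    ids[sample(i - 1L, k)]
  }))
  syn <- lapply(seq_len(n), function(i)
    if (runif(1) < synonym_rate) paste0("alias rd ", i) else character())
  ontology_graph(tibble::tibble(
    id = ids, label = paste("rd node", seq_len(n)),
    parents = parents, synonyms = syn, obsolete = FALSE))
}

# the four-node diamond-ish DAG used throughout the examples:
# A -> {B, C}, B -> D
tiny_dag <- function() {
  ontology_graph(tibble::tibble(
    id = c("T:A", "T:B", "T:C", "T:D"),
    label = c("Alpha", "Beta", "Gamma", "Delta"),
    parents = list(character(), "T:A", "T:A", "T:B"),
    synonyms = list(character(), "ACE inhibitor", character(), character()),
    obsolete = FALSE))
}

hancestro_graph <- function() {
  read_obo(system.file("extdata", "hancestro-snippet.obo",
                       package = "metaharmony"))
}

treatment_map <- function() {
  read_curation_map(system.file("extdata", "maps", "treatment.csv",
                                package = "metaharmony"))
}

# small cohort dictionary + ontology shared by consensus/recovery tests
sim_ontology <- function(seed = 11L) {
  make_toy_ontology(depth = 2, branching = 3, prefixes = c("SEXO", "DISO"),
                    seed = seed, synonym_rate = 0.2, multiparent_rate = 0)
}

sim_dictionary <- function(graph) {
  roots <- graph$terms$id[lengths(graph$parents[graph$terms$id]) == 0L]
  sexo_root <- roots[startsWith(roots, "SEXO")]
  diso_root <- roots[startsWith(roots, "DISO")]
  data_dictionary(
    attribute_spec("sex", "single", dynamic_enum_nodes = sexo_root),
    attribute_spec("disease", "single", dynamic_enum_nodes = diso_root),
    attribute_spec("treatment", "multi", dynamic_enum_nodes = diso_root),
    attribute_spec("age", "single", value_class = "numeric-with-unit",
                   unit_attribute = "age_unit"),
    attribute_spec("age_unit", "single", value_class = "free-text"),
    version = "test")
}
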
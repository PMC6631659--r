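# Shared builders for miniature ontologies and repositories. Everything is
# generated in code; no fixture files.

obo_from_edges <- function(ids, parents, names = NULL, obsolete = character()) {
  # parents: named list id -> character vector of parent ids
  stanzas <- vapply(ids, function(id) {
    lines <- c("[Term]", paste0("id: ", id),
               paste0("name: ", if (is.null(names)) paste("term", id) else names[[id]]))
    for (p in parents[[id]]) lines <- c(lines, paste0("is_a: ", p))
    if (id %in% obsolete) lines <- c(lines, "is_obsolete: true")
    paste(lines, collapse = "\n")
  }, character(1))
  paste0("format-version: 1.2\n\n", paste(stanzas, collapse = "\n\n"), "\n")
}

diamond_ontology <- function() {
  # A is_a {B, C}; B is_a D; C is_a D
  parse_obo(obo_from_edges(
    ids = c("X:0000004", "X:0000002", "X:0000003", "X:0000001"),
    parents = list("X:0000004" = character(),
                   "X:0000002" = "X:0000004",
                   "X:0000003" = "X:0000004",
                   "X:0000001" = c("X:0000002", "X:0000003"))
  ))
}

random_dag_ontology <- function(n, p_edge = 0.15) {
  # nodes only point at earlier nodes, so the graph is acyclic
  ids <- sprintf("X:%07d", seq_len(n))
  parents <- list()
  parents[[ids[1L]]] <- character()
  for (i in seq_len(n)[-1L]) {
    pool <- ids[seq_len(i - 1L)]
    chosen <- pool[stats::runif(length(pool)) < p_edge]
    if (!length(chosen)) chosen <- sample(pool, 1L)
    parents[[ids[i]]] <- chosen
  }
  parse_obo(obo_from_edges(ids, parents))
}

# independent closure oracle: reachability on the is_a edge list via igraph
igraph_closure <- function(ontology, term_id, mode) {
  edges <- character()
  for (t in ontology$terms) {
    for (p in t$parents) edges <- c(edges, t$term_id, p)
  }
  g <- igraph::make_graph(edges, directed = TRUE)
  g <- g + igraph::vertices(setdiff(names(ontology$terms), igraph::V(g)$name))
  reach <- igraph::subcomponent(g, term_id, mode = mode)$name
  sort(setdiff(reach, term_id))
}

test_ontologies <- function() {
  fx <- make_fixture(seed = 42, n_terms = 15, n_genotypes = 3, n_annotations = 6)
  list(omp = fx$ontology, eco = fx$eco_ontology)
}

# minimal valid annotation on a fresh two-genotype repo; override fields to
# break exactly one rule at a time
make_valid_annotation <- function(overrides = list(), repo_tweak = NULL) {
  onts <- test_ontologies()
  repo <- omp_repository()
  g1 <- new_genotype(repo, "MG1655", "rph-1")
  g2 <- new_genotype(repo, "mutant", "rph-1 tonA21")
  ref <- new_annotation(repo, g1$genotype_id, "OMP:0000300", "ECO:0000006",
                        "PMID:1000001",
                        conditions = omp_conditions(medium = "LB", temperature = "37C"),
                        timestamp = "2019-01-01T00:00:00")
  fields <- list(
    repo = repo, genotype_id = g2$genotype_id, omp_term_id = "OMP:0007441",
    eco_id = "ECO:0000006", reference = "PMID:1000002",
    conditions = omp_conditions(medium = "LB", temperature = "37C"),
    extensions = list(omp_extension("RO:0002503", "CHEBI:74728")),
    relative_to = ref$annotation_id, timestamp = "2019-01-02T00:00:00"
  )
  for (f in names(overrides)) fields[f] <- list(overrides[[f]])
  ann <- do.call(new_annotation, fields)
  if (!is.null(repo_tweak)) ann <- repo_tweak(repo, ann, ref)
  list(ann = ann, repo = repo, ref = ref, ontologies = onts)
}

random_token_string <- function(n_tokens) {
  vocab <- c("thr-1", "leuB6", "lacY1", "tonA21", "recA56", "araD139",
             "galK2", "rpsL31", "lacZ::Tn10", "acrR51::Tn10", "ampC101",
             "fliC726", "marR2", "proA2", "hisG4")
  seps <- c(" ", ", ", "; ", "  ", ",", ";")
  toks <- sample(vocab, n_tokens, replace = TRUE)
  paste(toks, collapse = sample(seps, 1L))
}
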
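beta_lactam_repo <- function() {
  fx <- make_fixture(seed = 13, n_terms = 15, n_genotypes = 2,
                     n_annotations = 2)
  repo <- omp_repository()
  g <- new_genotype(repo, "MG1655", "rph-1")
  ref <- new_annotation(repo, g$genotype_id, "OMP:0000336", "ECO:0000006",
                        "PMID:1", timestamp = "2019-01-01T00:00:00")
  child <- new_annotation(repo, g$genotype_id, "OMP:0000337", "ECO:0000006",
                          "PMID:2", relative_to = ref$annotation_id,
                          timestamp = "2019-01-01T00:00:01")
  list(repo = repo, ontology = fx$ontology, ref = ref, child = child)
}

test_that("descendant propagation retrieves annotations to child terms", {
  bl <- beta_lactam_repo()
  # annotation to the child term only
  repo <- omp_repository()
  g <- new_genotype(repo, "MG1655", "rph-1")
  a_ref <- new_annotation(repo, g$genotype_id, "OMP:0000300", "ECO:0000006",
                          "PMID:1", timestamp = "2019-01-01T00:00:00")
  a_child <- new_annotation(repo, g$genotype_id, "OMP:0000337", "ECO:0000006",
                            "PMID:2", relative_to = a_ref$annotation_id,
                            timestamp = "2019-01-01T00:00:01")
  with_desc <- annotations_to_term(repo, bl$ontology, "OMP:0000336",
                                   include_descendants = TRUE)
  expect_equal(vapply(with_desc, `[[`, character(1), "annotation_id"),
               a_child$annotation_id)
  without <- annotations_to_term(repo, bl$ontology, "OMP:0000336",
                                 include_descendants = FALSE)
  expect_length(without, 0L)

  # query on a leaf equals exact-match query
  leaf_desc <- annotations_to_term(repo, bl$ontology, "OMP:0000337", TRUE)
  leaf_exact <- annotations_to_term(repo, bl$ontology, "OMP:0000337", FALSE)
  expect_equal(leaf_desc, leaf_exact)

  expect_error(annotations_to_term(repo, bl$ontology, "OMP:1111111"),
               "unknown term")
})

test_that("term queries equal a brute-force closure scan on a random DAG", {
  set.seed(50)
  ont <- random_dag_ontology(50)
  ids <- names(ont$terms)
  repo <- omp_repository()
  g <- new_genotype(repo, "s", "rph-1")
  for (i in 1:30) {
    new_annotation(repo, g$genotype_id, sample(ids, 1L), "ECO:0000006",
                   paste0("PMID:", i), timestamp = "2019-01-01T00:00:00")
  }
  for (term in sample(ids, 10L)) {
    closure <- c(term, descendants(ont, term))
    oracle <- sort(names(Filter(function(a) a$omp_term_id %in% closure,
                                repo$annotations)))
    got <- annotations_to_term(repo, ont, term, include_descendants = TRUE)
    expect_equal(vapply(got, `[[`, character(1), "annotation_id"), oracle)
    # monotonicity: descendant-propagated results contain the exact matches
    exact <- annotations_to_term(repo, ont, term, include_descendants = FALSE)
    expect_true(all(vapply(exact, `[[`, character(1), "annotation_id") %in%
                      vapply(got, `[[`, character(1), "annotation_id")))
  }
})

test_that("filters conjoin criteria and match extension targets", {
  fx <- make_fixture(seed = 21, n_terms = 20, n_genotypes = 4,
                     n_annotations = 12)
  repo <- fx$repo

  # the acriflavine worked example is retrievable by its extension target
  hits <- filter_annotations(repo, list(extension_target = "CHEBI:74728"))
  expect_true(length(hits) >= 1L)
  expect_true(all(vapply(hits, function(a) {
    any(vapply(a$extensions, function(e) "CHEBI:74728" %in% e$target_ids,
               logical(1)))
  }, logical(1))))

  # empty criteria returns everything
  expect_length(filter_annotations(repo), length(repo$annotations))

  # conjunction equals the intersection of single-criterion results
  gid <- repo$annotations[[1L]]$genotype_id
  eco <- repo$annotations[[1L]]$eco_id
  both <- filter_annotations(repo, list(genotype_id = gid, eco_id = eco))
  only_g <- filter_annotations(repo, list(genotype_id = gid))
  only_e <- filter_annotations(repo, list(eco_id = eco))
  ids_of <- function(s) vapply(s, `[[`, character(1), "annotation_id")
  expect_setequal(ids_of(both), intersect(ids_of(only_g), ids_of(only_e)))

  # has_relative_to partitions the corpus
  with_ref <- filter_annotations(repo, list(has_relative_to = TRUE))
  without_ref <- filter_annotations(repo, list(has_relative_to = FALSE))
  expect_equal(length(with_ref) + length(without_ref),
               length(repo$annotations))

  expect_error(filter_annotations(repo, list(species = "E. coli")),
               "unknown criterion")
})

test_that("query results are insensitive to annotation insertion order", {
  build <- function(order) {
    repo <- omp_repository()
    g <- new_genotype(repo, "s", "rph-1")
    specs <- list(
      list(term = "OMP:0000005", ref = "PMID:1"),
      list(term = "OMP:0000336", ref = "PMID:2"),
      list(term = "OMP:0000300", ref = "PMID:3")
    )[order]
    for (s in specs) {
      new_annotation(repo, g$genotype_id, s$term, "ECO:0000006", s$ref,
                     timestamp = "2019-01-01T00:00:00")
    }
    repo
  }
  ont <- make_fixture(seed = 1, n_terms = 12, n_genotypes = 1,
                      n_annotations = 1, frac_dependent = 0)$ontology
  r1 <- build(1:3)
  r2 <- build(3:1)
  terms_of <- function(repo) {
    vapply(annotations_to_term(repo, ont, "OMP:0000300", TRUE),
           `[[`, character(1), "omp_term_id")
  }
  expect_setequal(terms_of(r1), terms_of(r2))
})

test_that("Not-qualified annotations are retrieved but flagged in output", {
  repo <- omp_repository()
  g <- new_genotype(repo, "s", "rph-1")
  new_annotation(repo, g$genotype_id, "OMP:0000005", "ECO:0000006", "PMID:1",
                 qualifier = "Not", timestamp = "2019-01-01T00:00:00")
  hits <- filter_annotations(repo, list(qualifier = "Not"))
  expect_length(hits, 1L)
  expect_match(paste(capture.output(print(hits)), collapse = "\n"),
               "NOT-qualified")
})
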
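test_that("OBO parsing models the supported tags and strips decorations", {
  ont <- parse_obo("[Term]\nid: X:0000001\nname: root")
  expect_length(ont$terms, 1L)
  expect_equal(lookup_term(ont, "X:0000001")$name, "root")
  expect_length(lookup_term(ont, "X:0000001")$parents, 0L)

  txt <- paste(
    "format-version: 1.4",
    "data-version: 2019-07-15",
    "",
    "[Typedef]",
    "id: part_of",
    "",
    "[Term]",
    "id: OMP:0000039",
    "name: cell size phenotype",
    "",
    "[Term]",
    "id: OMP:0000041",
    "name: increased cell size",
    'def: "An altered cell size phenotype where the volume of a cell or cells is increased relative to a designated control" [OMP:curators]',
    "is_a: OMP:0000039 ! cell size phenotype",
    "relationship: towards OMP:0000039 ! comment",
    "synonym: \"bigger cells\" EXACT []",
    sep = "\n")
  ont <- parse_obo(txt)
  expect_equal(ont$release_tag, "2019-07-15")
  t41 <- lookup_term(ont, "OMP:0000041")
  expect_equal(t41$name, "increased cell size")
  expect_equal(t41$definition,
               paste("An altered cell size phenotype where the volume of a cell",
                     "or cells is increased relative to a designated control"))
  expect_equal(t41$parents, "OMP:0000039")  # "! comment" stripped
  expect_equal(t41$relationships[[1L]],
               list(relation = "towards", target = "OMP:0000039"))

  obs <- parse_obo(paste(
    "[Term]\nid: X:0000001\nname: root",
    "[Term]\nid: X:0000002\nname: old\nis_a: X:0000001\nis_obsolete: true",
    sep = "\n\n"))
  t2 <- lookup_term(obs, "X:0000002")
  expect_true(t2$is_obsolete)
  expect_length(t2$parents, 0L)  # obsolete terms leave the closure graph
})

test_that("malformed OBO input raises informative parse errors", {
  expect_error(parse_obo("[Term]\nname: anonymous"), "line 1")
  expect_error(
    parse_obo("[Term]\nid: X:0000001\nname: a\n\n[Term]\nid: X:0000001\nname: b"),
    "duplicate term id: X:0000001")
  expect_error(parse_obo("[Term]\nid: X:0000001\nname: a\nis_a: X:0000009"),
               "X:0000009")
  cyc <- paste("[Term]\nid: X:0000001\nname: a\nis_a: X:0000002",
               "[Term]\nid: X:0000002\nname: b\nis_a: X:0000001", sep = "\n\n")
  expect_error(parse_obo(cyc), "cyclic")
})

test_that("lookup is exact-match with NULL for unknown ids", {
  ont <- diamond_ontology()
  expect_equal(lookup_term(ont, "X:0000002")$term_id, "X:0000002")
  expect_null(lookup_term(ont, "OMP:9999999"))
})

test_that("ancestor and descendant closure matches hand-computed cases", {
  chain <- parse_obo(paste(
    "[Term]\nid: X:0000003\nname: C",
    "[Term]\nid: X:0000002\nname: B\nis_a: X:0000003",
    "[Term]\nid: X:0000001\nname: A\nis_a: X:0000002", sep = "\n\n"))
  expect_setequal(ancestors(chain, "X:0000001"), c("X:0000002", "X:0000003"))
  expect_length(ancestors(chain, "X:0000003"), 0L)  # root
  expect_length(descendants(chain, "X:0000001"), 0L)  # leaf

  dia <- diamond_ontology()
  expect_setequal(ancestors(dia, "X:0000001"),
                  c("X:0000002", "X:0000003", "X:0000004"))
  expect_setequal(descendants(dia, "X:0000004"),
                  c("X:0000001", "X:0000002", "X:0000003"))
  expect_error(ancestors(dia, "X:0000099"), "unknown term")
})

test_that("closure equals an independent graph-reachability oracle on random DAGs", {
  skip_if_not_installed("igraph")
  set.seed(421)
  for (rep in 1:5) {
    ont <- random_dag_ontology(sample(20:60, 1L))
    for (id in names(ont$terms)) {
      expect_equal(ancestors(ont, id), igraph_closure(ont, id, "out"))
      expect_equal(descendants(ont, id), igraph_closure(ont, id, "in"))
    }
  }
})

test_that("ancestors and descendants are dual and contain direct relatives", {
  set.seed(99)
  ont <- random_dag_ontology(40)
  ids <- names(ont$terms)
  for (x in ids) {
    for (y in ancestors(ont, x)) expect_true(x %in% descendants(ont, y))
    kids <- ids[vapply(ont$terms, function(t) x %in% t$parents, logical(1))]
    expect_true(all(kids %in% descendants(ont, x)))
  }
})

test_that("parse -> serialize -> parse is lossless for the modeled fields", {
  set.seed(7)
  ont <- random_dag_ontology(25)
  ont2 <- parse_obo(write_obo(ont), release_tag = ont$release_tag)
  expect_equal(ont2$terms[sort(names(ont2$terms))],
               ont$terms[sort(names(ont$terms))])
  fx <- make_fixture(seed = 3, n_terms = 20, n_genotypes = 2, n_annotations = 4)
  ont3 <- parse_obo(write_obo(fx$ontology))
  expect_equal(ont3$terms[sort(names(ont3$terms))],
               fx$ontology$terms[sort(names(fx$ontology$terms))])
})

test_that("dependent-term detection follows config roots and the name heuristic", {
  fx <- make_fixture(seed = 1, n_terms = 12, n_genotypes = 2, n_annotations = 4)
  ont <- fx$ontology
  expect_true(is_dependent_term(ont, "OMP:0000041"))   # "increased cell size"
  expect_false(is_dependent_term(ont, "OMP:0000005"))  # "motile", no flagged roots
  expect_false(is_dependent_term(ont, "OMP:0000336"))  # neutral name

  # config outranks the heuristic: neutral-named term under a flagged root
  conf <- omp_config(dependent_roots = "OMP:0000336", name_heuristic = FALSE)
  expect_true(is_dependent_term(ont, "OMP:0000336", conf))
  # descendants of the root inherit the classification
  expect_true(is_dependent_term(ont, "OMP:0000338", conf))
  # with the heuristic off and no roots, prefix names are not dependent
  expect_false(is_dependent_term(ont, "OMP:0000041",
                                 omp_config(name_heuristic = FALSE)))
  expect_error(is_dependent_term(ont, "OMP:1234567"), "unknown term")
})
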
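test_that("genotype registration assigns sequential OMP_ST ids from 1", {
  repo <- omp_repository()
  g1 <- new_genotype(repo, "MG1655", "rph-1")
  expect_equal(g1$genotype_id, "OMP_ST:0000001")
  g2 <- new_genotype(repo, "W3110", "rph-1 IN(rrnD-rrnE)1")
  expect_equal(g2$genotype_id, "OMP_ST:0000002")

  gv <- new_genotype(repo, "collection", "pooled", is_virtual = TRUE)
  expect_true(repo$genotypes[[gv$genotype_id]]$is_virtual)

  expect_error(new_genotype(repo, "orphan", "x", ancestry = "OMP_ST:0009999"),
               "ancestry")
  child <- new_genotype(repo, "derived", "rph-1 tonA21", ancestry = g1$genotype_id)
  expect_equal(repo$genotypes[[child$genotype_id]]$ancestry, g1$genotype_id)
})

test_that("annotation creation assigns OMP_AN ids, suffixes, and history", {
  repo <- omp_repository()
  g <- new_genotype(repo, "MG1655", "rph-1")
  a1 <- new_annotation(repo, g$genotype_id, "OMP:0000005", "ECO:0000006",
                       "PMID:1", timestamp = "2019-01-01T00:00:00")
  expect_equal(a1$annotation_id, "OMP_AN:0000001")
  expect_length(a1$history, 1L)
  expect_equal(a1$history[[1L]]$action, "created")

  a2 <- new_annotation(repo, g$genotype_id, "OMP:0000005", "ECO:0000006",
                       "PMID:2", suffix = "IGS", timestamp = "2019-01-01T00:00:00")
  expect_equal(a2$annotation_id, "OMP_AN:0000002-IGS")

  a3 <- new_annotation(repo, g$genotype_id, "OMP:0007441", "ECO:0000006",
                       "PMID:3",
                       extensions = list(omp_extension("RO:0002503", "CHEBI:74728")),
                       relative_to = a1$annotation_id,
                       timestamp = "2019-01-01T00:00:01")
  expect_equal(a3$extensions[[1L]]$relation_id, "RO:0002503")
  expect_equal(a3$extensions[[1L]]$target_ids, "CHEBI:74728")

  expect_error(new_annotation(repo, "OMP_ST:0000099", "OMP:0000005",
                              "ECO:0000006", "PMID:4"), "genotype not found")
  expect_error(new_annotation(repo, g$genotype_id, "OMP:0000005",
                              "ECO:0000006", "PMID:4",
                              relative_to = "OMP_AN:0000099"),
               "relative_to annotation not found")
})

test_that("revision updates in place, keeps the id, and records prior values", {
  repo <- omp_repository()
  g <- new_genotype(repo, "MG1655", "rph-1")
  a <- new_annotation(repo, g$genotype_id, "OMP:0000005", "ECO:0000006",
                      "PMID:1", timestamp = "2019-01-01T00:00:00")

  r1 <- revise_annotation(repo, a$annotation_id, list(notes = "checked"),
                          timestamp = "2019-01-02T00:00:00")
  expect_equal(r1$annotation_id, a$annotation_id)
  expect_length(r1$history, 2L)
  expect_equal(r1$notes, "checked")

  r2 <- revise_annotation(repo, a$annotation_id,
                          list(omp_term_id = "OMP:0000041"),
                          timestamp = "2019-01-03T00:00:00")
  expect_equal(r2$omp_term_id, "OMP:0000041")
  # old value recoverable from the event note
  expect_match(r2$history[[3L]]$note, "omp_term_id: OMP:0000005")

  expect_error(revise_annotation(repo, a$annotation_id,
                                 list(annotation_id = "OMP_AN:0000042")),
               "immutable")
  expect_error(revise_annotation(repo, a$annotation_id, list(notes = "late"),
                                 timestamp = "2018-12-31T00:00:00"),
               "precedes")
  expect_error(revise_annotation(repo, "OMP_AN:0000099", list(notes = "x")),
               "unknown annotation")
})

test_that("ids stay unique and monotone across creation and tombstoned deletion", {
  repo <- omp_repository()
  for (i in 1:50) new_genotype(repo, paste0("s", i), "rph-1")
  gids <- names(repo$genotypes)
  expect_equal(anyDuplicated(gids), 0L)
  expect_equal(gids, sprintf("OMP_ST:%07d", 1:50))

  delete_record(repo, "OMP_ST:0000050")
  g_next <- new_genotype(repo, "after-delete", "rph-1")
  expect_equal(g_next$genotype_id, "OMP_ST:0000051")  # no id reuse
  expect_true("OMP_ST:0000050" %in% repo$tombstones)
  expect_error(delete_record(repo, "OMP_ST:0000050"), "unknown id")

  g <- repo$genotypes[[1L]]
  for (i in 1:50) {
    new_annotation(repo, g$genotype_id, "OMP:0000005", "ECO:0000006",
                   paste0("PMID:", i), timestamp = "2019-01-01T00:00:00")
  }
  expect_equal(anyDuplicated(names(repo$annotations)), 0L)
  ints <- as.integer(sub("OMP_AN:", "", names(repo$annotations)))
  expect_true(all(diff(ints) > 0))
})

test_that("referential integrity survives a randomized create/revise stress run", {
  set.seed(2024)
  repo <- omp_repository()
  fx_terms <- c("OMP:0000005", "OMP:0000300", "OMP:0000336")
  for (step in 1:300) {
    op <- sample(c("genotype", "annotation", "revise"), 1L,
                 prob = c(0.2, 0.5, 0.3))
    if (op == "genotype" || !length(repo$genotypes)) {
      new_genotype(repo, paste0("s", step), random_token_string(3L))
    } else if (op == "annotation") {
      refs <- names(repo$annotations)
      new_annotation(repo, sample(names(repo$genotypes), 1L),
                     sample(fx_terms, 1L), "ECO:0000006",
                     paste0("PMID:", step),
                     relative_to = if (length(refs) && stats::runif(1) < 0.4)
                       sample(refs, 1L) else NULL,
                     timestamp = sprintf("2019-01-01T00:%02d:%02d",
                                         step %/% 60, step %% 60))
    } else if (length(repo$annotations)) {
      revise_annotation(repo, sample(names(repo$annotations), 1L),
                        list(notes = paste("step", step)),
                        timestamp = "2030-01-01T00:00:00")
    }
  }
  for (a in repo$annotations) {
    expect_false(is.null(repo$genotypes[[a$genotype_id]]))
    if (!is.null(a$relative_to)) {
      expect_false(is.null(repo$annotations[[a$relative_to]]))
    }
    expect_equal(a$history[[1L]]$action, "created")
  }
})

test_that("relative_to cycles are rejected at insertion and revision time", {
  repo <- omp_repository()
  g <- new_genotype(repo, "MG1655", "rph-1")
  a <- new_annotation(repo, g$genotype_id, "OMP:0000005", "ECO:0000006",
                      "PMID:1", timestamp = "2019-01-01T00:00:00")
  b <- new_annotation(repo, g$genotype_id, "OMP:0000041", "ECO:0000006",
                      "PMID:2", relative_to = a$annotation_id,
                      timestamp = "2019-01-01T00:00:01")
  # closing the 2-cycle a -> b -> a must fail
  expect_error(revise_annotation(repo, a$annotation_id,
                                 list(relative_to = b$annotation_id),
                                 timestamp = "2019-01-02T00:00:00"),
               "cycle")
  # self-reference is also a cycle
  expect_error(revise_annotation(repo, a$annotation_id,
                                 list(relative_to = a$annotation_id),
                                 timestamp = "2019-01-02T00:00:00"),
               "cycle")
})
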
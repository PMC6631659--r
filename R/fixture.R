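## Seeded generator for a self-contained miniature corpus: a mini
## phenotype ontology (with the named exemplar terms), a mini evidence
## ontology, and a repository of genotypes and annotations that passes
## validation. Used by the test suite and the `fixture` CLI subcommand.

core_omp_stanzas <- function() {
  c(
    "[Term]\nid: OMP:0000001\nname: microbial phenotype",
    "[Term]\nid: OMP:0000002\nname: morphology phenotype\nis_a: OMP:0000001",
    "[Term]\nid: OMP:0000005\nname: motile\nis_a: OMP:0000001",
    "[Term]\nid: OMP:0000039\nname: cell size phenotype\nis_a: OMP:0000002",
    paste0("[Term]\nid: OMP:0000041\nname: increased cell size\n",
           'def: "An altered cell size phenotype where the volume of a cell ',
           'or cells is increased relative to a designated control" []\n',
           "is_a: OMP:0000039"),
    "[Term]\nid: OMP:0000300\nname: resistance to chemical phenotype\nis_a: OMP:0000001",
    "[Term]\nid: OMP:0000336\nname: beta-lactam resistance phenotype\nis_a: OMP:0000300",
    "[Term]\nid: OMP:0000337\nname: increased beta-lactam resistance\nis_a: OMP:0000336",
    "[Term]\nid: OMP:0000338\nname: decreased beta-lactam resistance\nis_a: OMP:0000336",
    "[Term]\nid: OMP:0007441\nname: increased resistance to chemical\nis_a: OMP:0000300"
  )
}

CORE_OMP_IDS <- c("OMP:0000001", "OMP:0000002", "OMP:0000005", "OMP:0000039",
                  "OMP:0000041", "OMP:0000300", "OMP:0000336", "OMP:0000337",
                  "OMP:0000338", "OMP:0007441")
INDEPENDENT_TERM_POOL <- c("OMP:0000005", "OMP:0000300", "OMP:0000336")
DEPENDENT_TERM_POOL <- c("OMP:0000041", "OMP:0000337", "OMP:0000338",
                         "OMP:0007441")

eco_obo_text <- function() {
  paste0(paste(c(
    "format-version: 1.2",
    "data-version: fixture-eco-1",
    "",
    "[Term]\nid: ECO:0000000\nname: evidence",
    "[Term]\nid: ECO:0000006\nname: experimental evidence\nis_a: ECO:0000000",
    "[Term]\nid: ECO:0000021\nname: physical interaction evidence\nis_a: ECO:0000006",
    "[Term]\nid: ECO:0001845\nname: cell population optical density evidence\nis_a: ECO:0000006"
  ), collapse = "\n"), "\n")
}

ECO_POOL <- c("ECO:0000006", "ECO:0000021", "ECO:0001845")

CONDITION_POOL <- list(
  function() omp_conditions(medium = "LB", temperature = "37C"),
  function() omp_conditions(medium = "LB", temperature = "42C"),
  function() omp_conditions(medium = "M9-glucose", temperature = "37C", pH = "7.0"),
  function() omp_conditions(ENVO = "ENVO:01001059", other = "microaerobic"),
  function() omp_conditions(medium = "LB-agar", temperature = "30C")
)

fixture_timestamp <- function(i) sprintf("2019-07-15T%02d:%02d:%02d",
                                         (i %/% 3600) %% 24, (i %/% 60) %% 60,
                                         i %% 60)

#' Generate a miniature ontology + annotation corpus
#'
#' Deterministic for a given seed. The mini phenotype ontology always
#' contains the exemplar terms: `OMP:0000041` "increased cell size" (a
#' dependent term), `OMP:0000336` "beta-lactam resistance phenotype" with
#' child terms, the independent term "motile", and `OMP:0007441`
#' "increased resistance to chemical"; filler terms are attached beneath
#' random parents up to `n_terms`. A mini evidence ontology ships four
#' ECO-style terms. The repository always contains the worked acriflavine
#' example when `n_annotations >= 2`: an annotation to the
#' increased-resistance term carrying the extension
#' `RO:0002503(CHEBI:74728)` with a `relative_to` reference. Dependent
#' annotations receive valid reference chains, qualifier use is exercised
#' where the corpus is large enough, about 20% of annotations carry
#' extensions with CHEBI-style targets, and every generated annotation
#' passes [validate_annotation()] without errors.
#'
#' @param seed Integer seed.
#' @param n_terms Total phenotype terms (>= the 10 core terms; smaller
#'   values keep just the core).
#' @param n_genotypes Number of strains (>= 1); the third is a virtual
#'   collection strain when present.
#' @param n_annotations Number of annotations (>= 1).
#' @param frac_dependent Target fraction of dependent annotations
#'   (default 0.5). Dependent annotations need a reference, so
#'   `frac_dependent > 0` requires `n_annotations >= 2`.
#' @return A list with `obo_text` and `eco_obo_text` (OBO flat-file
#'   strings), `ontology` and `eco_ontology` (parsed), and `repo` (an
#'   [omp_repository()]).
#' @export
make_fixture <- function(seed = 1L, n_terms = 30L, n_genotypes = 5L,
                         n_annotations = 20L, frac_dependent = 0.5) {
  stopifnot(n_terms >= 1L, n_genotypes >= 1L, n_annotations >= 1L,
            frac_dependent >= 0, frac_dependent <= 1)
  if (frac_dependent > 0 && n_annotations < 2L) {
    stop("dependent annotations need a reference annotation: ",
         "n_annotations must be >= 2 when frac_dependent > 0", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  ## --- mini phenotype ontology ---
  stanzas <- core_omp_stanzas()
  extra <- max(0L, n_terms - length(CORE_OMP_IDS))
  ids <- CORE_OMP_IDS
  if (extra > 0L) {
    for (k in seq_len(extra)) {
      id <- sprintf("OMP:09%05d", k)
      parent <- sample(ids, 1L)
      stanzas <- c(stanzas, paste0("[Term]\nid: ", id,
                                   "\nname: synthetic phenotype ", k,
                                   "\nis_a: ", parent))
      ids <- c(ids, id)
    }
  }
  obo <- paste0("format-version: 1.2\ndata-version: fixture-omp-1\n\n",
                paste(stanzas, collapse = "\n\n"), "\n")
  ontology <- parse_obo(obo)
  eco_txt <- eco_obo_text()
  eco <- parse_obo(eco_txt)

  ## --- genotypes ---
  repo <- omp_repository()
  wt <- new_genotype(repo, label = "MG1655", genotype_text = "rph-1",
                     source = "CGSC", reference = "PMID:9278503")
  alleles <- c("acrR51::Tn10", "tonA21", "lacZ::Tn5", "ampC101", "fliC726",
               "recA56", "araD139", "galK2", "rpsL31", "marR2")
  for (k in seq_len(n_genotypes - 1L)) {
    if (k == 2L) {
      new_genotype(repo, label = "collection-average",
                   genotype_text = "pooled-insertion-library",
                   is_virtual = TRUE, reference = "PMID:16738554")
    } else {
      extra_alleles <- sample(alleles, min(1L + (k %% 3L), length(alleles)))
      new_genotype(repo,
                   label = paste0("strain-", k),
                   genotype_text = paste(c("rph-1", extra_alleles), collapse = " "),
                   ancestry = wt$genotype_id,
                   reference = sprintf("PMID:%07d", 2000000L + k))
    }
  }
  genotype_ids <- names(repo$genotypes)
  nonvirtual <- genotype_ids[!vapply(repo$genotypes, function(g) g$is_virtual,
                                     logical(1))[genotype_ids]]

  ## --- annotations ---
  n_dep <- min(floor(frac_dependent * n_annotations), n_annotations - 1L)
  n_ref <- n_annotations - n_dep
  ts_i <- 0L
  next_ts <- function() { ts_i <<- ts_i + 1L; fixture_timestamp(ts_i) }

  ref_ids <- character()
  ## reference (independent) annotations; the first is the acriflavine
  ## example's reference on the wild type
  for (k in seq_len(n_ref)) {
    gid <- if (k == 1L) wt$genotype_id else sample(genotype_ids, 1L)
    term <- if (k == 1L) "OMP:0000300" else sample(INDEPENDENT_TERM_POOL, 1L)
    a <- new_annotation(
      repo, genotype_id = gid, omp_term_id = term,
      eco_id = sample(ECO_POOL, 1L),
      reference = sprintf("PMID:%07d", 3000000L + k),
      conditions = CONDITION_POOL[[1L + (k - 1L) %% length(CONDITION_POOL)]](),
      extensions = if (stats::runif(1) < 0.2) {
        list(omp_extension("RO:0002503",
                           sprintf("CHEBI:%05d", sample.int(99999L, 1L))))
      } else list(),
      editor = "fixture", timestamp = next_ts()
    )
    ref_ids <- c(ref_ids, a$annotation_id)
  }

  dep_made <- 0L
  if (n_dep >= 1L) {
    ## worked example: increased resistance to acriflavine hydrochloride
    gid <- if (length(nonvirtual) > 1L) nonvirtual[2L] else nonvirtual[1L]
    new_annotation(
      repo, genotype_id = gid, omp_term_id = "OMP:0007441",
      eco_id = "ECO:0000006", reference = "PMID:8416900",
      conditions = omp_conditions(medium = "LB", temperature = "37C"),
      extensions = list(omp_extension("RO:0002503", "CHEBI:74728")),
      relative_to = ref_ids[1L],
      notes = "increased resistance to acriflavine hydrochloride",
      editor = "fixture", timestamp = next_ts()
    )
    dep_made <- 1L
  }
  ## qualifier exemplars among the remaining dependent slots
  if (n_dep - dep_made >= 1L && length(nonvirtual) >= 2L) {
    ref_ann <- repo$annotations[[ref_ids[1L]]]
    other <- setdiff(nonvirtual, ref_ann$genotype_id)[1L]
    new_annotation(
      repo, genotype_id = other, omp_term_id = ref_ann$omp_term_id,
      eco_id = sample(ECO_POOL, 1L), reference = "PMID:3001001",
      conditions = ref_ann$conditions,
      relative_to = ref_ann$annotation_id,
      qualifier = "Same phenotype as reference strain",
      editor = "fixture", timestamp = next_ts()
    )
    dep_made <- dep_made + 1L
  }
  if (n_dep - dep_made >= 1L) {
    ref_ann <- repo$annotations[[ref_ids[1L]]]
    new_annotation(
      repo, genotype_id = ref_ann$genotype_id,
      omp_term_id = ref_ann$omp_term_id,
      eco_id = sample(ECO_POOL, 1L), reference = "PMID:3001002",
      conditions = omp_conditions(medium = "LB", temperature = "42C"),
      relative_to = ref_ann$annotation_id,
      qualifier = "Same phenotype as in reference condition",
      editor = "fixture", timestamp = next_ts()
    )
    dep_made <- dep_made + 1L
  }
  ## remaining dependent annotations
  while (dep_made < n_dep) {
    dep_made <- dep_made + 1L
    term <- sample(DEPENDENT_TERM_POOL, 1L)
    new_annotation(
      repo, genotype_id = sample(genotype_ids, 1L), omp_term_id = term,
      eco_id = sample(ECO_POOL, 1L),
      reference = sprintf("PMID:%07d", 4000000L + dep_made),
      conditions = CONDITION_POOL[[sample.int(length(CONDITION_POOL), 1L)]](),
      extensions = if (stats::runif(1) < 0.2) {
        list(omp_extension("RO:0002503",
                           sprintf("CHEBI:%05d", sample.int(99999L, 1L))))
      } else list(),
      relative_to = sample(ref_ids, 1L),
      editor = "fixture", timestamp = next_ts()
    )
  }

  list(obo_text = obo, eco_obo_text = eco_txt, ontology = ontology,
       eco_ontology = eco, repo = repo)
}
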
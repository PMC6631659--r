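# ompannot

Microbial phenotypes are not properties of a gene: they are what a
particular **genotype** does in a particular **environment**. Capturing them
in a computable form therefore takes more than attaching an ontology term to
a gene — an annotation needs a stable strain identifier, the growth
conditions, the evidence behind the observation, and (for comparative
phenotypes like *increased* resistance) a pointer to the reference
observation it is being compared against.

`ompannot` implements that annotation standard as an R library plus a
command-line tool, for curators and tool builders working with
OMP-style phenotype ontologies (Ontology of Microbial Phenotypes),
ECO evidence terms, and related OBO vocabularies. It provides:

* **Ontology store** — an OBO flat-file parser producing a term graph with
  `ancestors()`/`descendants()` closure, plus a release archive
  (`omp_archive()`, `load_release()`, `term_history()`) that keeps one
  version-history record per term per release.
* **Annotation model** — genotype/strain records (`OMP_ST:` ids, allele
  text, ancestry, virtual-collection strains) and annotation records
  (`OMP_AN:` ids, phenotype term, extensions, `relative_to`, qualifier,
  ECO evidence, PMID reference, revision history), held in an
  integrity-checked `omp_repository()`.
* **Validation engine** — the standard's rules R1–R10: term existence and
  obsolescence, the dependent-phenotype requirement (a term like
  "increased cell size" is meaningless without a designated control, so it
  must carry a `relative_to` reference), the three-value qualifier
  vocabulary and its per-qualifier semantics, extension and CURIE
  well-formedness, and repository-level referential integrity.
* **Difference calculator** — `diff_annotations()` tokenizes the genotype
  and conditions fields of a dependent annotation and its reference and
  reports unique-token differences in both directions.
* **Query engine** — `annotations_to_term()` with descendant propagation
  (ask for the beta-lactam resistance parent term, get annotations to any
  child), and `filter_annotations()` over genotype, qualifier, evidence,
  and extension targets.
* **Release formats** — paired tab-delimited annotation + genotype files
  modeled on GO's GPAD+GPI release system, a lossless JSON export with a
  shipped schema, and a seeded miniature-corpus generator
  (`make_fixture()`) for testing and demonstration.

Post-composition is central to the standard: rather than minting one
pre-composed ontology term per chemical, an annotation refines an
intermediate term at annotation time with an **extension** — a Relations
Ontology relation paired with target identifiers, e.g.
`RO:0002503` ("towards") linking `CHEBI:74728` (acriflavine hydrochloride)
to a term for increased chemical resistance.

## Worked example

A wild-type reference observation and a dependent annotation recording
increased acriflavine resistance in a `tonA21` mutant:

```r
library(ompannot)

fx   <- make_fixture(seed = 7)          # mini OMP + ECO ontologies
onts <- list(omp = fx$ontology, eco = fx$eco_ontology)

repo <- omp_repository()
wt  <- new_genotype(repo, "MG1655", "thr-1 leuB6 lacY1")
mut <- new_genotype(repo, "tonA21 mutant", "thr-1 leuB6 lacY1 tonA21",
                    ancestry = wt$genotype_id)
ref <- new_annotation(repo, wt$genotype_id, "OMP:0000300", "ECO:0000006",
                      "PMID:8416900",
                      conditions = omp_conditions(medium = "LB", temperature = "37C"),
                      timestamp = "2019-07-15T09:00:00")
acr <- new_annotation(repo, mut$genotype_id, "OMP:0007441", "ECO:0000006",
                      "PMID:8416900",
                      conditions = omp_conditions(medium = "LB", temperature = "37C"),
                      extensions = list(omp_extension("RO:0002503", "CHEBI:74728")),
                      relative_to = ref$annotation_id,
                      timestamp = "2019-07-15T09:05:00")
print(acr)
#> OMP_AN:0000002 | OMP_ST:0000002 | OMP:0007441 relative_to OMP_AN:0000001
#>   evidence: ECO:0000006 ref: PMID:8416900
#>   extensions: RO:0002503(CHEBI:74728)
#>   conditions: medium=LB|temperature=37C
#>   history: 1 event(s)
```

The repository passes validation, and the difference calculator isolates
the allele that separates the mutant from its reference:

```r
validate_repository(repo, onts)
#> no violations

diff_annotations(acr$annotation_id, repo)
#> genotype only in current   : tonA21
#> genotype only in reference : (none)
#> conditions only in current   : (none)
#> conditions only in reference : (none)
```

The release writer renders the extension in its GPAD-style cell
(`RO:0002503(CHEBI:74728)`, column 6 of the annotation file):

```r
strsplit(write_release(repo, onts)$annotation_tsv, "\n")[[1]][3]
#> OMP_AN:0000002  OMP_ST:0000002    OMP:0007441  OMP_AN:0000001  RO:0002503(CHEBI:74728)  ECO:0000006  PMID:8416900  medium=LB|temperature=37C    2019-07-15T09:05:00  2019-07-15T09:05:00
```

## Command line

A thin wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "omp.R", package = "ompannot"))') \
  fixture --seed 7 --out-dir corpus/
# then: validate / query / diff / export / import / stats, e.g.
... validate --ontology corpus/omp.obo --eco corpus/eco.obo \
    --annotations corpus/annotations.tsv --genotypes corpus/genotypes.tsv
```

`validate` exits nonzero iff any error-severity violation exists; `query
--term OMP:0000336 --descendants` retrieves annotations at an intermediate
grouping term and everything below it.

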
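Package: ompannot
Title: Microbial Phenotype Annotation with OMP-Style Ontologies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A typed data model, validation engine, and release tooling for
    phenotype annotations of microbial genotypes built on OBO-format
    ontologies such as the Ontology of Microbial Phenotypes (OMP) and the
    Evidence and Conclusion Ontology (ECO). Parses OBO flat files into term
    graphs with ancestor/descendant closure and per-release term version
    history; houses annotation, genotype, and condition records with stable
    auto-incremented identifiers and revision history; enforces the
    annotation standard's rules (term existence, dependent-phenotype
    references, qualifier semantics, extension well-formedness); computes
    token-level genotype and condition differences between a dependent
    annotation and its reference; answers ontology-aware queries with
    descendant propagation; and reads and writes paired tab-delimited
    release files modeled on GPAD+GPI as well as a JSON export. Includes a
    seeded generator for miniature ontology and annotation corpora, and a
    command-line interface for curator-style workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
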
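---
title: "The microbial phenotype annotation standard in ompannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microbial phenotype annotation standard in ompannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ompannot)
```

## The annotation model

A phenotype is the manifestation of a genotype in an environment. An
annotation record in `ompannot` therefore couples five groups of fields:

1. **Identity** — a stable `OMP_AN:<integer>` id, with an optional
   `-suffix` for records contributed by outside groups. Stable ids exist so
   corrections can be tracked and so one annotation can reference another.
2. **Subject** — an `OMP_ST:` genotype id plus the conditions under which
   the phenotype was observed. Strain records carry free-text allele
   listings, optional ancestry, provenance, and a virtual-strain flag for
   the pooled "average of a mutant collection" references used by
   high-throughput fitness studies.
3. **Phenotype** — an ontology term, optional extensions, an optional
   `relative_to` reference, and an optional qualifier.
4. **Evidence** — an ECO evidence term and a literature reference,
   normally a `PMID:` CURIE.
5. **Metadata** — an append-only history of created/revised events and
   free-text notes.

Two design commitments shape the model. First, **dependent vs independent
phenotypes**: "motile" stands alone, but "increased cell size" is defined
only relative to a designated control, so dependent annotations must point
at their reference annotation. Second, **post-composition**: rather than
pre-composing one ontology term per chemical or phage, an annotation
refines an intermediate-level term with extensions — relation/target
pairs such as `RO:0002503` ("towards") → `CHEBI:74728` — leaving the
ontology itself untouched.

The repository object has reference semantics (an environment), mirroring
how a curation database behaves: `new_annotation()` and
`revise_annotation()` mutate it in place, identifiers are assigned by
auto-increment starting at 1, and deletion tombstones an id forever rather
than recycling it. Rendered ids are zero-padded to seven digits (the OBO
convention); parsing accepts any width. Revisions update fields in place
under the same id and store the prior value of each changed field in the
history event's note — one current row per annotation, with enough
breadcrumbs to reconstruct what changed, rather than full field-level
versioning.

## Dependent-term detection

The ontology carries no machine-readable marker separating dependent from
independent terms, so classification is configurable
(`omp_config()`): a term is dependent when it or any ancestor appears in a
configured dependent-root list, or — with the default name heuristic
enabled — when its name begins with *increased*, *decreased*, *altered*,
*abolished*, or *same*. The configured root list always applies and
outranks the heuristic; the heuristic default is ON because those five
prefixes are how comparative terms are actually named in practice. Users
with curated ontologies can supply roots and switch the heuristic off.

## Validation rules

`validate_annotation()` returns every violation, never throws, and orders
findings by (annotation id, rule id) so output is deterministic. Rules
R1–R10 cover term existence and obsolescence (obsolete-term use is an
*error*: a curation-quality stance, chosen deliberately where the standard
is silent), the dependent-phenotype reference requirement, reference
resolution and acyclicity, the closed three-value qualifier vocabulary,
the two structural qualifier semantics, extension and CURIE
well-formedness, the PMID expectation (non-PMID CURIEs are a warning, not
an error), and condition-key/ENVO shape checks. R6/R7 compare genotype
*ids*, not genotype text: isogenicity is not computable from the recorded
fields, and real corpora contain deliberate non-isogenic comparisons.
"Not" imposes no structural requirement — it is purely semantic ("tested
for, but not observed").

Repository-level checks extend the vocabulary with `G1` (dangling
genotype/ancestry references, e.g. after a tombstoned deletion), `G2`
(duplicate ids, defensive only), and `V1`, a warning for annotations on
virtual strains sitting on qualifier-free dependent chains longer than two
links, where the averaged reference makes long chains hard to interpret.
`relative_to` cycles are reported under R4, naming every participant.

## The difference calculator

`diff_annotations()` resolves the reference annotation, fetches the two
genotype texts and the two conditions lists, tokenizes each, and reports
set differences in both directions with first-occurrence order preserved.
The tokenizer splits on runs of whitespace, commas, and semicolons — a
concrete choice where the standard requires only "a regular expression" —
and is case-preserving and case-sensitive, since allele symbols are
case-meaningful (`recA` vs `RecA`). Conditions entries are rendered
`key=value` before tokenization so a changed value surfaces as one whole
entry; a value containing internal whitespace will tokenize into pieces,
which is why the fixture generator and the examples use compact values
(`37C`, `M9-glucose`). No attempt is made to identify the causative
allele: in a non-isogenic comparison every differing token is listed.

## Ontology store and archive

The OBO parser models `id`, `name`, `def`, `is_a`, `relationship`,
`is_obsolete`, and `namespace`; all other tags and stanza types are
ignored silently, which is sufficient for annotation-support use and keeps
the parser honest about what it round-trips (`write_obo()` →
`parse_obo()` is term-by-term lossless for exactly those fields).
Decorations are stripped: definition quotes and dbxref brackets, and
trailing `! comment` text on targets. A cyclic `is_a` graph is a hard
parse-time error, because closure is undefined on cycles; obsolete terms
retain no parents, removing them from closure. `ancestors()` and
`descendants()` are breadth-first walks over the edge list; the test suite
checks them against an independent graph-reachability oracle (igraph) on
random DAGs of up to 200 terms.

The release archive keeps one history record per term per loaded release —
release-driven granularity, matching an archive fed by periodic ontology
releases rather than by individual edits. Tags must be strictly
increasing, so history order never depends on load order bookkeeping.

## Release formats

The tab-delimited export is a pair of files modeled on GO's GPAD+GPI
system: a 12-column annotation file and an 8-column genotype file, each
with a `!`-prefixed header, rows sorted bytewise by id, and empty
optionals as empty fields. The extension micro-grammar
`REL(T1,T2)|REL2(T3)` mirrors GPAD's extension syntax. Tab, pipe, comma,
and parenthesis characters are forbidden in free-text values at write time
rather than escaped — a simpler contract that keeps the files trivially
parseable. TSV reading collapses history to created/modified dates (the
only dates the file carries); the JSON export is the lossless format,
serializing full history event lists, and conforms to the schema shipped
in `inst/schema/release-schema.json`, checked by the package's own
structural validator (`validate_release_json()`) covering the keyword
subset the schema uses. Export is byte-deterministic for a given
repository, which is what makes the round-trip guarantees testable as byte
identity.

## The fixture generator

`make_fixture()` emulates a small curated corpus: a mini phenotype
ontology that always contains the exemplar terms (increased cell size, the
beta-lactam resistance parent with children, motile, increased resistance
to chemical), a four-term evidence ontology, a wild-type strain with
derived mutants carrying classic *E. coli* allele names, one virtual
collection strain, and a corpus in which roughly half the annotations are
dependent with valid reference chains, qualifier use is exercised, and
about 20% of annotations carry chemical extensions. The acriflavine
worked example — `OMP:0007441` with `RO:0002503(CHEBI:74728)` — is always
present when at least two annotations are requested. Defaults (30 terms, 5
genotypes, 20 annotations, 50% dependent) are the corpus scale used
throughout the documentation and checks.

What the generator does *not* emulate: real ontology scale (the live
phenotype ontology has ~1,900 terms), free-text messiness in genotype
fields, conflicting or revised curation, ENVO/ChEBI terms resolved against
real releases, and quantitative fitness scores (excluded from the standard
by design). Passing tests on fixture corpora therefore demonstrate the
mechanics of the standard — identity, validation, closure, diffing,
round-tripping — not robustness to dirty literature-derived data.

## Numerical and degenerate-input choices

* Closure on a term with no parents/children is the empty set; the term
  itself is never a member of its own closure.
* `tokenize("")` is `character()`; a diff of identical inputs is four
  empty vectors.
* Violation output ordering uses bytewise (`radix`) sorting, so results do
  not depend on locale.
* `read_release()` resumes id counters past the largest imported integer,
  preserving no-reuse across export/import cycles.
* Problem sizes in the checks — 100 random DAGs of up to 200 terms, 1,000
  random token pairs, 50 round-trip repositories — were chosen as the
  smallest sizes that exercise the combinatorics convincingly; all
  verification completes in well under a minute.

## Known limitations

* The OBO dialect is the annotation-support subset; OWL, cross-ontology
  imports, and reasoning beyond `is_a` closure are out of scope.
* ENVO and ChEBI identifiers are shape-checked only, unless the caller
  loads those ontologies; the conditions field is a placeholder by design.
* Extension relations are matched exactly, not through the Relations
  Ontology hierarchy.
* JSON-LD context generation is not implemented; the JSON export is plain
  JSON.
* The CLI is a curator-workflow convenience, not a server: it reads and
  writes explicit file paths and never touches the network.
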
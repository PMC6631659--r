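## Ontology-aware retrieval over the repository.

#' Retrieve annotations to an ontology term, optionally with descendants
#'
#' With `include_descendants = TRUE` the query propagates down the `is_a`
#' graph, which supports retrieval at intermediate grouping terms — e.g.
#' asking for a beta-lactam resistance parent term returns annotations
#' made to any of its child terms. Without it, only exact term matches are
#' returned.
#'
#' @param repo An [omp_repository()].
#' @param ontology The phenotype `omp_ontology`.
#' @param term_id Term CURIE; must be present in the ontology.
#' @param include_descendants Logical (default `FALSE`).
#' @return An `omp_annotation_set` (list of annotations ordered by
#'   annotation id). Annotations carrying the "Not" qualifier are included
#'   but flagged when printed, since dropping them silently would invert
#'   their meaning.
#' @export
annotations_to_term <- function(repo, ontology, term_id,
                                include_descendants = FALSE) {
  stopifnot(inherits(repo, "omp_repository"), inherits(ontology, "omp_ontology"))
  if (is.null(lookup_term(ontology, term_id))) {
    stop("unknown term id: ", term_id, call. = FALSE)
  }
  wanted <- term_id
  if (isTRUE(include_descendants)) {
    wanted <- c(wanted, descendants(ontology, term_id))
  }
  hits <- Filter(function(a) a$omp_term_id %in% wanted, repo$annotations)
  as_annotation_set(hits)
}

FILTER_KEYS <- c("genotype_id", "qualifier", "eco_id", "reference",
                 "extension_target", "has_relative_to")

#' Filter annotations by a conjunction of criteria
#'
#' All given criteria must hold. `extension_target` matches when any
#' extension's target list contains the given CURIE (matching is exact on
#' CURIEs; relation hierarchies are not consulted). `has_relative_to`
#' is logical.
#'
#' @param repo An [omp_repository()].
#' @param criteria Named list over `genotype_id`, `qualifier`, `eco_id`,
#'   `reference`, `extension_target`, `has_relative_to`. An empty list
#'   returns every annotation.
#' @return An `omp_annotation_set` ordered by annotation id.
#' @export
filter_annotations <- function(repo, criteria = list()) {
  stopifnot(inherits(repo, "omp_repository"))
  bad <- setdiff(names(criteria), FILTER_KEYS)
  if (length(bad)) {
    stop("unknown criterion key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- function(a) {
    for (k in names(criteria)) {
      want <- criteria[[k]]
      ok <- switch(
        k,
        genotype_id = identical(a$genotype_id, want),
        qualifier = identical(a$qualifier, want),
        eco_id = identical(a$eco_id, want),
        reference = identical(a$reference, want),
        extension_target = any(vapply(a$extensions,
                                      function(e) want %in% e$target_ids,
                                      logical(1))),
        has_relative_to = identical(!is.null(a$relative_to), isTRUE(want))
      )
      if (!ok) return(FALSE)
    }
    TRUE
  }
  as_annotation_set(Filter(keep, repo$annotations))
}

as_annotation_set <- function(anns) {
  anns <- anns[order(names(anns))]
  structure(unname(anns), ids = names(anns), class = "omp_annotation_set")
}

#' @export
print.omp_annotation_set <- function(x, ...) {
  cat("<omp_annotation_set>", length(x), "annotation(s)\n")
  for (a in x) {
    flag <- if (identical(a$qualifier, "Not")) " [NOT-qualified]" else ""
    cat(" ", a$annotation_id, a$omp_term_id, a$genotype_id, flag, "\n")
  }
  invisible(x)
}

#' @export
length.omp_annotation_set <- function(x) length(unclass(x))
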
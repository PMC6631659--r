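## Difference calculation between a dependent annotation and its
## reference: tokenize the genotype and conditions fields and compare
## arrays of unique tokens.

#' Tokenize free text into unique, order-preserving tokens
#'
#' Splits on runs of whitespace, commas, and semicolons; empty tokens are
#' dropped, duplicates removed keeping the first occurrence, and case is
#' preserved (comparisons downstream are case-sensitive).
#'
#' @param text A character scalar (empty allowed).
#' @return Character vector of unique tokens in first-occurrence order.
#' @examples
#' tokenize("thr-1 leuB6 lacY1")
#' tokenize("lacZ::Tn10, lacZ::Tn10; araD139")
#' @export
tokenize <- function(text) {
  if (is.null(text) || !length(text) || is.na(text)) return(character())
  toks <- strsplit(as.character(text), "[\\s,;]+", perl = TRUE)[[1L]]
  unique(toks[nzchar(toks)])
}

#' Token-level differences between an annotation and its reference
#'
#' Resolves the annotation's `relative_to` reference, then compares (a)
#' the genotype text of the two annotations' strains and (b) the two
#' annotations' conditions, each entry rendered as `key=value` before
#' tokenization so a changed value surfaces as a whole-entry difference.
#' All differing tokens are reported in both directions; no attempt is
#' made to single out a causative allele — in a non-isogenic comparison
#' every allele difference is listed even though only one is likely
#' causative.
#'
#' @param ann An `omp_annotation`, or an annotation id.
#' @param repo The [omp_repository()] holding it and its reference.
#' @return An object of class `omp_diff` with ordered unique token vectors
#'   `genotype_only_current`, `genotype_only_reference`,
#'   `conditions_only_current`, `conditions_only_reference`.
#' @export
diff_annotations <- function(ann, repo) {
  stopifnot(inherits(repo, "omp_repository"))
  if (is.character(ann)) {
    id <- ann
    ann <- repo$annotations[[id]]
    if (is.null(ann)) stop("unknown annotation id: ", id, call. = FALSE)
  }
  if (is.null(ann$relative_to)) {
    stop("annotation ", ann$annotation_id, " has no relative_to reference",
         call. = FALSE)
  }
  ref <- repo$annotations[[ann$relative_to]]
  if (is.null(ref)) {
    stop("relative_to ", ann$relative_to, " does not resolve", call. = FALSE)
  }
  cur_geno <- repo$genotypes[[ann$genotype_id]]
  ref_geno <- repo$genotypes[[ref$genotype_id]]
  if (is.null(cur_geno) || is.null(ref_geno)) {
    stop("genotype record missing for ",
         if (is.null(cur_geno)) ann$genotype_id else ref$genotype_id,
         call. = FALSE)
  }
  g_cur <- tokenize(cur_geno$genotype_text)
  g_ref <- tokenize(ref_geno$genotype_text)
  c_cur <- tokenize(conditions_text(ann$conditions))
  c_ref <- tokenize(conditions_text(ref$conditions))
  structure(
    list(genotype_only_current = setdiff(g_cur, g_ref),
         genotype_only_reference = setdiff(g_ref, g_cur),
         conditions_only_current = setdiff(c_cur, c_ref),
         conditions_only_reference = setdiff(c_ref, c_cur)),
    class = "omp_diff"
  )
}

conditions_text <- function(cond) {
  if (!nrow(cond)) return("")
  paste(paste0(cond$key, "=", cond$value), collapse = " ")
}

#' @export
print.omp_diff <- function(x, ...) {
  section <- function(label, toks) {
    cat(label, ":", if (length(toks)) paste(toks, collapse = " ") else "(none)", "\n")
  }
  section("genotype only in current  ", x$genotype_only_current)
  section("genotype only in reference", x$genotype_only_reference)
  section("conditions only in current  ", x$conditions_only_current)
  section("conditions only in reference", x$conditions_only_reference)
  invisible(x)
}
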
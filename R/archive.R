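## Release archive: per-term version history across successive ontology
## releases, in the spirit of a release-driven term archive.

#' Create an empty ontology release archive
#'
#' The archive accumulates successive ontology releases and keeps, for
#' every term, one history record per loaded release in which the term
#' appears. Name changes and obsoletions are visible as successive
#' records. Granularity is per release, not per field change: the archive
#' is fed by periodic ontology releases.
#'
#' @return An object of class `omp_archive`.
#' @seealso [load_release()], [term_history()]
#' @export
omp_archive <- function() {
  structure(list(release_tags = character(), history = list()),
            class = "omp_archive")
}

#' Load an ontology release into an archive
#'
#' Release tags must be strictly increasing across calls; re-loading an
#' already-loaded tag (or loading out of order) is an error.
#'
#' @param archive An [omp_archive()].
#' @param ontology An `omp_ontology` whose `release_tag` labels the release.
#' @return The updated archive.
#' @export
load_release <- function(archive, ontology) {
  stopifnot(inherits(archive, "omp_archive"), inherits(ontology, "omp_ontology"))
  tag <- ontology$release_tag
  if (tag %in% archive$release_tags) {
    stop("release ", tag, " already loaded", call. = FALSE)
  }
  if (length(archive$release_tags) && tag <= archive$release_tags[length(archive$release_tags)]) {
    stop("release tags must be strictly increasing: ", tag, " after ",
         archive$release_tags[length(archive$release_tags)], call. = FALSE)
  }
  archive$release_tags <- c(archive$release_tags, tag)
  for (t in ontology$terms) {
    rec <- data.frame(release_tag = tag, name = t$name,
                      definition = t$definition, is_obsolete = t$is_obsolete,
                      stringsAsFactors = FALSE)
    archive$history[[t$term_id]] <- rbind(archive$history[[t$term_id]], rec)
  }
  archive
}

#' Version history of a term across loaded releases
#'
#' @param archive An [omp_archive()].
#' @param term_id Term CURIE.
#' @return An object of class `omp_term_history`: a data frame with one
#'   row per loaded release containing the term (columns `release_tag`,
#'   `name`, `definition`, `is_obsolete`), ordered by load order. Zero rows
#'   when the term never appeared.
#' @export
term_history <- function(archive, term_id) {
  stopifnot(inherits(archive, "omp_archive"))
  h <- archive$history[[term_id]]
  if (is.null(h)) {
    h <- data.frame(release_tag = character(), name = character(),
                    definition = character(), is_obsolete = logical(),
                    stringsAsFactors = FALSE)
  }
  structure(h, term_id = term_id, class = c("omp_term_history", "data.frame"))
}

#' @export
print.omp_archive <- function(x, ...) {
  cat("<omp_archive>", length(x$release_tags), "release(s),",
      length(x$history), "term(s) tracked\n")
  if (length(x$release_tags)) {
    cat("  releases:", paste(x$release_tags, collapse = ", "), "\n")
  }
  invisible(x)
}
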
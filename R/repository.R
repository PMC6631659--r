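## Annotation model: genotype/strain records, annotation records with
## revision history, stable auto-incremented identifiers, and the
## integrity-checked repository holding them.

GENOTYPE_ID_RE <- "^OMP_ST:[0-9]+$"
ANNOTATION_ID_RE <- "^OMP_AN:[0-9]+(-[A-Za-z0-9]+)?$"
QUALIFIERS <- c("Not",
                "Same phenotype as reference strain",
                "Same phenotype as in reference condition")
CONDITION_KEYS <- c("ENVO", "temperature", "pH", "medium", "other")

#' Allowed qualifier values
#'
#' The three controlled qualifier strings: `"Not"` (phenotype tested for
#' but not observed), `"Same phenotype as reference strain"` (a genotype
#' change does not change the phenotype), and `"Same phenotype as in
#' reference condition"` (an environment change does not change the
#' phenotype).
#'
#' @return Character vector of length 3.
#' @export
omp_qualifiers <- function() QUALIFIERS

#' Environment/conditions entries for an annotation
#'
#' Ordered key-value pairs describing the growth environment. Allowed keys
#' are `"ENVO"`, `"temperature"`, `"pH"`, `"medium"`, and `"other"`; keys
#' may repeat. `ENVO` values are expected to be ENVO CURIEs. Entries are
#' kept as entered, not resolved against an environment ontology.
#'
#' @param ... Named character values, e.g.
#'   `omp_conditions(medium = "LB", temperature = "37C")`.
#' @return An object of class `omp_conditions`: a data frame with columns
#'   `key` and `value`.
#' @export
omp_conditions <- function(...) {
  args <- list(...)
  keys <- names(args)
  if (length(args) && (is.null(keys) || any(!nzchar(keys)))) {
    stop("all condition entries must be named", call. = FALSE)
  }
  structure(
    data.frame(key = as.character(keys),
               value = as.character(unlist(args, use.names = FALSE)),
               stringsAsFactors = FALSE),
    class = c("omp_conditions", "data.frame")
  )
}

conditions_from_pairs <- function(keys, values) {
  structure(data.frame(key = as.character(keys), value = as.character(values),
                       stringsAsFactors = FALSE),
            class = c("omp_conditions", "data.frame"))
}

#' An annotation extension (post-composition unit)
#'
#' Pairs a Relations Ontology relation with one or more target
#' identifiers, refining a broad ontology term at annotation time — e.g.
#' `omp_extension("RO:0002503", "CHEBI:74728")` specializes a chemical
#' resistance phenotype to acriflavine hydrochloride via the "towards"
#' relation.
#'
#' @param relation_id Relation CURIE (typically `RO:…`).
#' @param target_ids Character vector of one or more target CURIEs.
#' @return An object of class `omp_extension`.
#' @export
omp_extension <- function(relation_id, target_ids) {
  target_ids <- as.character(target_ids)
  if (!length(target_ids)) stop("extension needs at least one target", call. = FALSE)
  structure(list(relation_id = as.character(relation_id), target_ids = target_ids),
            class = "omp_extension")
}

#' Create an empty annotation repository
#'
#' The repository is the integrity-checked collection of genotypes and
#' annotations that validation, queries, diffs, and exports operate on. It
#' has reference semantics: [new_genotype()], [new_annotation()], and
#' [revise_annotation()] modify it in place. Identifier counters start at
#' 1 and never reuse a number; deletion tombstones an id rather than
#' recycling it.
#'
#' @return An object of class `omp_repository`.
#' @export
omp_repository <- function() {
  repo <- new.env(parent = emptyenv())
  repo$genotypes <- list()
  repo$annotations <- list()
  repo$next_genotype <- 1L
  repo$next_annotation <- 1L
  repo$tombstones <- character()
  class(repo) <- "omp_repository"
  repo
}

render_id <- function(prefix, n, suffix = NULL) {
  id <- sprintf("%s:%07d", prefix, n)
  if (!is.null(suffix) && nzchar(suffix)) id <- paste0(id, "-", suffix)
  id
}

#' Register a new genotype/strain record
#'
#' Assigns the next `OMP_ST:` identifier and stores the record. The
#' genotype text is a free-text, whitespace-separated list of alleles and
#' episomes; ancestry optionally points at the parent strain's record.
#' Virtual strains stand for the average behavior of a mutant collection
#' in high-throughput fitness studies.
#'
#' @param repo An [omp_repository()], modified in place.
#' @param label Short strain label, e.g. `"MG1655"`.
#' @param genotype_text Allele/episome listing, e.g. `"thr-1 leuB6 lacY1"`.
#' @param ancestry Optional `OMP_ST:` id of the parent strain; must resolve.
#' @param source Optional free text on where to obtain the strain.
#' @param reference Optional CURIE (usually `PMID:…`) describing the strain.
#' @param external_ids Character vector of external CURIEs (stock-center,
#'   genome accessions).
#' @param is_virtual Logical; virtual-collection strain flag.
#' @return The stored genotype record (class `omp_genotype`), invisibly
#'   carrying its new id in `$genotype_id`.
#' @export
new_genotype <- function(repo, label, genotype_text = "", ancestry = NULL,
                         source = NULL, reference = NULL,
                         external_ids = character(), is_virtual = FALSE) {
  stopifnot(inherits(repo, "omp_repository"))
  if (!is.null(ancestry)) {
    if (is.null(repo$genotypes[[ancestry]])) {
      stop("ancestry genotype not found: ", ancestry, call. = FALSE)
    }
  }
  id <- render_id("OMP_ST", repo$next_genotype)
  repo$next_genotype <- repo$next_genotype + 1L
  g <- structure(
    list(genotype_id = id, label = as.character(label),
         genotype_text = as.character(genotype_text),
         ancestry = ancestry, source = source, reference = reference,
         external_ids = as.character(external_ids),
         is_virtual = isTRUE(is_virtual)),
    class = "omp_genotype"
  )
  repo$genotypes[[id]] <- g
  invisible(g)
}

history_event <- function(timestamp, editor, action, note = NULL) {
  list(timestamp = as.character(timestamp), editor = as.character(editor),
       action = action, note = note)
}

#' Create a new phenotype annotation
#'
#' Assigns the next `OMP_AN:` identifier (with an optional `-suffix` used
#' for annotations contributed by other groups), appends a "created"
#' history event, and stores the record. Only structural checks run here
#' (the subject genotype and any `relative_to` reference must resolve, a
#' `relative_to` link must not close a cycle); the full annotation
#' standard is enforced by [validate_annotation()].
#'
#' @param repo An [omp_repository()], modified in place.
#' @param genotype_id `OMP_ST:` id of the annotated strain; must resolve.
#' @param omp_term_id Phenotype term CURIE (the pre-composed description).
#' @param eco_id Evidence term CURIE (`ECO:…`).
#' @param reference Source CURIE, usually `PMID:…`.
#' @param conditions An [omp_conditions()] record.
#' @param extensions List of [omp_extension()] records.
#' @param relative_to Optional `OMP_AN:` id of the reference annotation
#'   for a dependent phenotype.
#' @param qualifier Optional qualifier string; see [omp_qualifiers()].
#' @param notes Optional free-text notes.
#' @param editor Curator name for the history event.
#' @param timestamp ISO-8601 timestamp for the history event.
#' @param suffix Optional id suffix (letters/digits) appended as
#'   `"-suffix"`.
#' @return The stored annotation (class `omp_annotation`), invisibly.
#' @export
new_annotation <- function(repo, genotype_id, omp_term_id, eco_id, reference,
                           conditions = omp_conditions(),
                           extensions = list(), relative_to = NULL,
                           qualifier = NULL, notes = NULL,
                           editor = "curator",
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                           suffix = NULL) {
  stopifnot(inherits(repo, "omp_repository"))
  if (is.null(repo$genotypes[[genotype_id]])) {
    stop("genotype not found: ", genotype_id, call. = FALSE)
  }
  if (!is.null(relative_to) && is.null(repo$annotations[[relative_to]])) {
    stop("relative_to annotation not found: ", relative_to, call. = FALSE)
  }
  if (!is.null(suffix) && !grepl("^[A-Za-z0-9]+$", suffix)) {
    stop("suffix must be letters/digits only", call. = FALSE)
  }
  id <- render_id("OMP_AN", repo$next_annotation, suffix)
  repo$next_annotation <- repo$next_annotation + 1L
  ann <- structure(
    list(annotation_id = id, genotype_id = genotype_id,
         conditions = conditions, omp_term_id = omp_term_id,
         extensions = extensions, relative_to = relative_to,
         qualifier = qualifier, eco_id = eco_id, reference = reference,
         history = list(history_event(timestamp, editor, "created")),
         notes = notes),
    class = "omp_annotation"
  )
  check_relative_to_acyclic(repo, ann)
  repo$annotations[[id]] <- ann
  invisible(ann)
}

check_relative_to_acyclic <- function(repo, ann) {
  seen <- ann$annotation_id
  ref <- ann$relative_to
  while (!is.null(ref)) {
    if (ref %in% seen) {
      stop("relative_to cycle involving ", paste(seen, collapse = ", "),
           call. = FALSE)
    }
    seen <- c(seen, ref)
    nxt <- repo$annotations[[ref]]
    ref <- if (is.null(nxt)) NULL else nxt$relative_to
  }
  invisible(TRUE)
}

MUTABLE_ANNOTATION_FIELDS <- c("genotype_id", "conditions", "omp_term_id",
                               "extensions", "relative_to", "qualifier",
                               "eco_id", "reference", "notes")

#' Revise an existing annotation in place
#'
#' Updates mutable fields under the same annotation id and appends a
#' "revised" history event whose note records the prior value of each
#' changed field, so corrections stay traceable. The id and history are
#' immutable, and history timestamps must be monotonically non-decreasing.
#'
#' @param repo An [omp_repository()], modified in place.
#' @param annotation_id Id of the annotation to revise.
#' @param changes Named list of new values for mutable fields (any of
#'   `genotype_id`, `conditions`, `omp_term_id`, `extensions`,
#'   `relative_to`, `qualifier`, `eco_id`, `reference`, `notes`).
#' @param editor Curator making the change.
#' @param timestamp ISO-8601 timestamp; must not precede the last event.
#' @return The revised annotation, invisibly.
#' @export
revise_annotation <- function(repo, annotation_id, changes, editor = "curator",
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  stopifnot(inherits(repo, "omp_repository"))
  ann <- repo$annotations[[annotation_id]]
  if (is.null(ann)) stop("unknown annotation id: ", annotation_id, call. = FALSE)
  bad <- setdiff(names(changes), MUTABLE_ANNOTATION_FIELDS)
  if (length(bad)) {
    stop("immutable or unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  last_ts <- ann$history[[length(ann$history)]]$timestamp
  if (as.character(timestamp) < last_ts) {
    stop("revision timestamp ", timestamp, " precedes last history event ",
         last_ts, call. = FALSE)
  }
  prior <- vapply(names(changes), function(f) {
    paste0(f, ": ", render_field_value(ann[[f]]))
  }, character(1))
  for (f in names(changes)) ann[f] <- list(changes[[f]])
  check_relative_to_acyclic(repo, ann)
  ann$history[[length(ann$history) + 1L]] <-
    history_event(timestamp, editor, "revised",
                  note = paste0("was ", paste(prior, collapse = "; ")))
  repo$annotations[[annotation_id]] <- ann
  invisible(ann)
}

render_field_value <- function(v) {
  if (is.null(v)) return("<empty>")
  if (inherits(v, "omp_conditions")) return(render_conditions(v))
  if (is.list(v)) return(render_extensions(v))
  as.character(v)
}

#' Tombstone a genotype or annotation
#'
#' Removes the record but retires its id permanently: counters never move
#' backwards and a deleted id is never reassigned. Annotations referring
#' to a deleted record become dangling and are reported by
#' [validate_repository()].
#'
#' @param repo An [omp_repository()], modified in place.
#' @param id An `OMP_ST:` or `OMP_AN:` id present in the repository.
#' @return `TRUE`, invisibly.
#' @export
delete_record <- function(repo, id) {
  stopifnot(inherits(repo, "omp_repository"))
  if (!is.null(repo$genotypes[[id]])) {
    repo$genotypes[[id]] <- NULL
  } else if (!is.null(repo$annotations[[id]])) {
    repo$annotations[[id]] <- NULL
  } else {
    stop("unknown id: ", id, call. = FALSE)
  }
  repo$tombstones <- c(repo$tombstones, id)
  invisible(TRUE)
}

#' @export
print.omp_repository <- function(x, ...) {
  cat("<omp_repository>", length(x$genotypes), "genotype(s),",
      length(x$annotations), "annotation(s)\n")
  invisible(x)
}

#' @export
print.omp_annotation <- function(x, ...) {
  cat(x$annotation_id, "|", x$genotype_id, "|", x$omp_term_id)
  if (!is.null(x$qualifier)) cat(" [", x$qualifier, "]", sep = "")
  if (!is.null(x$relative_to)) cat(" relative_to", x$relative_to)
  cat("\n  evidence:", x$eco_id, "ref:", x$reference, "\n")
  if (length(x$extensions)) cat("  extensions:", render_extensions(x$extensions), "\n")
  if (nrow(x$conditions)) cat("  conditions:", render_conditions(x$conditions), "\n")
  cat("  history:", length(x$history), "event(s)\n")
  invisible(x)
}

#' @export
print.omp_genotype <- function(x, ...) {
  cat(x$genotype_id, x$label, if (x$is_virtual) "[virtual]" else "", "\n")
  if (nzchar(x$genotype_text)) cat("  genotype:", x$genotype_text, "\n")
  if (!is.null(x$ancestry)) cat("  ancestry:", x$ancestry, "\n")
  invisible(x)
}

render_conditions <- function(cond) {
  if (!nrow(cond)) return("")
  paste(paste0(cond$key, "=", cond$value), collapse = "|")
}

render_extensions <- function(exts) {
  if (!length(exts)) return("")
  paste(vapply(exts, function(e) {
    paste0(e$relation_id, "(", paste(e$target_ids, collapse = ","), ")")
  }, character(1)), collapse = "|")
}
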
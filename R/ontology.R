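## Ontology store: OBO flat-file parsing, term lookup, is_a closure,
## dependent-term classification.

CURIE_TERM_RE <- "^[A-Za-z_]+:[0-9]+$"
CURIE_RE <- "^[A-Za-z_][A-Za-z0-9_.]*:[A-Za-z0-9._-]+$"

#' Parse an OBO flat file into an ontology term graph
#'
#' Reads OBO 1.2/1.4-style text built from `[Term]` stanzas and returns an
#' in-memory ontology: a named list of terms plus a release tag. Only the
#' tags `id`, `name`, `def`, `is_a`, `relationship`, `is_obsolete`, and
#' `namespace` are interpreted; all other tags, and non-`[Term]` stanzas
#' such as `[Typedef]`, are ignored. Definition quotes and trailing dbxref
#' brackets are stripped, as is `! comment` text after `is_a` and
#' `relationship` targets. Obsolete terms keep no parents, so they never
#' participate in closure. A cyclic `is_a` graph over non-obsolete terms is
#' a parse-time error, as are stanzas without an `id` and duplicate ids.
#'
#' @param obo_text OBO flat-file content as a single string or a character
#'   vector of lines.
#' @param release_tag Release label (date or version) for this load. When
#'   `NULL`, the header's `data-version` is used if present, else
#'   `"unversioned"`.
#' @return An object of class `omp_ontology`: a list with `terms` (named
#'   list of `omp_term` records), `release_tag`, and `format_version`.
#' @seealso [lookup_term()], [ancestors()], [descendants()], [write_obo()]
#' @examples
#' ont <- parse_obo("[Term]\nid: X:0000001\nname: root")
#' lookup_term(ont, "X:0000001")$name
#' @export
parse_obo <- function(obo_text, release_tag = NULL) {
  lines <- if (length(obo_text) == 1L) strsplit(obo_text, "\n", fixed = TRUE)[[1L]] else obo_text
  lines <- sub("\r$", "", lines)

  ## header (everything before the first stanza)
  stanza_starts <- grep("^\\[", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1L] - 1L else length(lines)
  format_version <- "1.2"
  data_version <- NULL
  if (header_end > 0L) {
    for (ln in lines[seq_len(header_end)]) {
      if (startsWith(ln, "format-version:")) {
        format_version <- trimws(sub("^format-version:", "", ln))
      } else if (startsWith(ln, "data-version:")) {
        data_version <- trimws(sub("^data-version:", "", ln))
      }
    }
  }
  if (is.null(release_tag)) {
    release_tag <- if (!is.null(data_version)) data_version else "unversioned"
  }

  terms <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "[Term]") {
      start_line <- i
      i <- i + 1L
      tag_lines <- character()
      while (i <= n && !startsWith(lines[i], "[")) {
        tag_lines <- c(tag_lines, lines[i])
        i <- i + 1L
      }
      term <- parse_term_stanza(tag_lines, start_line)
      if (!is.null(terms[[term$term_id]])) {
        stop("duplicate term id: ", term$term_id, call. = FALSE)
      }
      terms[[term$term_id]] <- term
    } else {
      i <- i + 1L
    }
  }

  ## invariant: parents refer to term ids present in the same ontology
  for (term in terms) {
    missing <- setdiff(term$parents, names(terms))
    if (length(missing)) {
      stop("term ", term$term_id, " has is_a parent(s) not in the ontology: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  ont <- structure(
    list(terms = terms, release_tag = release_tag, format_version = format_version),
    class = "omp_ontology"
  )
  check_acyclic(ont)
  ont
}

parse_term_stanza <- function(tag_lines, start_line) {
  id <- NULL; name <- ""; definition <- ""; namespace <- ""
  parents <- character(); relationships <- list(); is_obsolete <- FALSE
  for (ln in tag_lines) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, "!")) next
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0L) next
    tag <- substr(ln, 1L, colon - 1L)
    val <- trimws(substr(ln, colon + 1L, nchar(ln)))
    if (tag == "id") {
      id <- val
    } else if (tag == "name") {
      name <- val
    } else if (tag == "def") {
      definition <- strip_def(val)
    } else if (tag == "is_a") {
      parents <- c(parents, strip_obo_comment(val))
    } else if (tag == "relationship") {
      parts <- strsplit(strip_obo_comment(val), "[[:space:]]+")[[1L]]
      if (length(parts) >= 2L) {
        relationships[[length(relationships) + 1L]] <-
          list(relation = parts[1L], target = parts[2L])
      }
    } else if (tag == "is_obsolete") {
      is_obsolete <- identical(tolower(val), "true")
    } else if (tag == "namespace") {
      namespace <- val
    }
    ## other tags ignored silently
  }
  if (is.null(id)) {
    stop("[Term] stanza at line ", start_line, " has no id", call. = FALSE)
  }
  if (!grepl(CURIE_TERM_RE, id)) {
    stop("term id ", id, " is not a PREFIX:digits CURIE", call. = FALSE)
  }
  if (is_obsolete) parents <- character()  # obsolete terms leave the closure graph
  structure(
    list(term_id = id, name = name, definition = definition,
         parents = unique(parents), relationships = relationships,
         is_obsolete = is_obsolete, namespace = namespace),
    class = "omp_term"
  )
}

strip_def <- function(val) {
  m <- regmatches(val, regexpr('"[^"]*"', val))
  if (length(m)) substr(m, 2L, nchar(m) - 1L) else val
}

strip_obo_comment <- function(val) trimws(sub("\\s*!.*$", "", val))

check_acyclic <- function(ontology) {
  ids <- names(ontology$terms)
  state <- integer(length(ids))  # 0 unseen, 1 in stack, 2 done
  names(state) <- ids
  visit <- function(id) {
    stack <- list(list(id = id, next_parent = 1L))
    state[[id]] <<- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      parents <- ontology$terms[[top$id]]$parents
      if (top$next_parent > length(parents)) {
        state[[top$id]] <<- 2L
        stack[[length(stack)]] <- NULL
      } else {
        p <- parents[top$next_parent]
        stack[[length(stack)]]$next_parent <- top$next_parent + 1L
        if (state[[p]] == 1L) {
          stop("cyclic is_a graph detected involving ", p, call. = FALSE)
        }
        if (state[[p]] == 0L) {
          state[[p]] <<- 1L
          stack[[length(stack) + 1L]] <- list(id = p, next_parent = 1L)
        }
      }
    }
  }
  for (id in ids) if (state[[id]] == 0L) visit(id)
  invisible(TRUE)
}

#' Look up a term by exact identifier
#'
#' @param ontology An `omp_ontology`.
#' @param term_id Term CURIE, e.g. `"OMP:0000041"`.
#' @return The `omp_term`, or `NULL` when the id is not present (obsolete
#'   terms are returned with `is_obsolete = TRUE`; policy is the caller's).
#' @export
lookup_term <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "omp_ontology"))
  ontology$terms[[term_id]]
}

#' @export
print.omp_ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) t$is_obsolete, logical(1)))
  cat("<omp_ontology> release", x$release_tag, "-", length(x$terms),
      "terms (", n_obs, "obsolete )\n")
  invisible(x)
}

#' @export
print.omp_term <- function(x, ...) {
  cat(x$term_id, x$name, if (x$is_obsolete) "[obsolete]" else "", "\n")
  if (nzchar(x$definition)) cat("  def: ", x$definition, "\n", sep = "")
  if (length(x$parents)) cat("  is_a:", paste(x$parents, collapse = ", "), "\n")
  invisible(x)
}

closure_walk <- function(ontology, term_id, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.null(ontology$terms[[term_id]])) {
    stop("unknown term id: ", term_id, call. = FALSE)
  }
  if (direction == "down") {
    children <- children_map(ontology)
    step <- function(id) children[[id]]
  } else {
    step <- function(id) ontology$terms[[id]]$parents
  }
  seen <- character()
  frontier <- term_id
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, step), use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, term_id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

children_map <- function(ontology) {
  cm <- lapply(ontology$terms, function(t) character())
  for (t in ontology$terms) {
    for (p in t$parents) cm[[p]] <- c(cm[[p]], t$term_id)
  }
  cm
}

#' Transitive ancestors of a term
#'
#' Breadth-first closure over `is_a` edges, excluding the term itself.
#'
#' @inheritParams lookup_term
#' @return Sorted character vector of ancestor CURIEs.
#' @export
ancestors <- function(ontology, term_id) closure_walk(ontology, term_id, "up")

#' Transitive descendants of a term
#'
#' Mirror of [ancestors()] on reversed `is_a` edges. Supports retrieval at
#' intermediate grouping terms (e.g. a beta-lactam resistance phenotype
#' parent and all of its child terms).
#'
#' @inheritParams lookup_term
#' @return Sorted character vector of descendant CURIEs.
#' @export
descendants <- function(ontology, term_id) closure_walk(ontology, term_id, "down")

#' Configuration for dependent-term detection and validation
#'
#' Dependent phenotypes (e.g. "increased cell size") are defined only
#' relative to another observation and so require a `relative_to`
#' reference; independent phenotypes (e.g. "motile") stand alone. The
#' ontology carries no machine-readable marker for the distinction, so the
#' package classifies terms by (a) membership of the term or any ancestor
#' in a configured set of dependent root terms, and (b) optionally, a name
#' heuristic: a term whose name begins with "increased", "decreased",
#' "altered", "abolished", or "same" is dependent.
#'
#' @param dependent_roots Character vector of term CURIEs acting as
#'   dependent roots.
#' @param name_heuristic Logical; apply the name-prefix heuristic
#'   (default `TRUE`).
#' @return An object of class `omp_config`.
#' @export
omp_config <- function(dependent_roots = character(), name_heuristic = TRUE) {
  structure(
    list(dependent_roots = as.character(dependent_roots),
         name_heuristic = isTRUE(name_heuristic)),
    class = "omp_config"
  )
}

DEPENDENT_NAME_PREFIXES <- c("increased", "decreased", "altered", "abolished", "same")

#' Is a term a dependent phenotype term?
#'
#' `TRUE` iff the term or any ancestor is in the config's dependent-root
#' set, or — when the name heuristic is enabled — the term's name begins
#' with one of the dependent prefixes. The configured root set always
#' applies regardless of the heuristic toggle.
#'
#' @inheritParams lookup_term
#' @param config An [omp_config()].
#' @return Logical scalar.
#' @export
is_dependent_term <- function(ontology, term_id, config = omp_config()) {
  term <- lookup_term(ontology, term_id)
  if (is.null(term)) stop("unknown term id: ", term_id, call. = FALSE)
  if (length(config$dependent_roots)) {
    lineage <- c(term_id, ancestors(ontology, term_id))
    if (any(lineage %in% config$dependent_roots)) return(TRUE)
  }
  if (config$name_heuristic) {
    first <- tolower(sub("[[:space:]].*$", "", term$name))
    if (first %in% DEPENDENT_NAME_PREFIXES) return(TRUE)
  }
  FALSE
}

#' Serialize an ontology back to OBO flat-file text
#'
#' Writes the fields the parser models (id, name, def, is_a, relationship,
#' is_obsolete, namespace); parsing the output reproduces the ontology
#' term-by-term.
#'
#' @param ontology An `omp_ontology`.
#' @return A single string of OBO text.
#' @export
write_obo <- function(ontology) {
  stopifnot(inherits(ontology, "omp_ontology"))
  out <- c(
    paste0("format-version: ", ontology$format_version),
    paste0("data-version: ", ontology$release_tag),
    ""
  )
  for (id in sort(names(ontology$terms))) {
    t <- ontology$terms[[id]]
    stanza <- c("[Term]", paste0("id: ", t$term_id), paste0("name: ", t$name))
    if (nzchar(t$definition)) stanza <- c(stanza, paste0('def: "', t$definition, '" []'))
    if (nzchar(t$namespace)) stanza <- c(stanza, paste0("namespace: ", t$namespace))
    for (p in t$parents) stanza <- c(stanza, paste0("is_a: ", p))
    for (r in t$relationships) {
      stanza <- c(stanza, paste0("relationship: ", r$relation, " ", r$target))
    }
    if (t$is_obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
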
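## Release formats: a pair of tab-delimited files (annotations +
## genotypes) modeled on the GPAD+GPI paired-file system, and a JSON
## export of the full data model. All files UTF-8 with LF line endings.

ANNOTATION_COLUMNS <- c("annotation_id", "genotype_id", "qualifier",
                        "omp_term_id", "relative_to", "extensions", "eco_id",
                        "reference", "conditions", "notes", "created_date",
                        "modified_date")
GENOTYPE_COLUMNS <- c("genotype_id", "label", "genotype_text", "ancestry",
                      "is_virtual", "source", "reference", "external_ids")

radix_sort <- function(x) {
  if (!length(x)) return(character())
  x[order(x, method = "radix")]
}

check_field_chars <- function(value, what) {
  if (grepl("[\t|,()]", value)) {
    stop("field value for ", what,
         " contains a forbidden character (tab, pipe, comma, or parenthesis): ",
         value, call. = FALSE)
  }
  value
}

opt <- function(x) if (is.null(x)) "" else as.character(x)

#' Write the paired tab-delimited release files
#'
#' Produces two tab-separated tables with `!`-prefixed header lines: one
#' row per annotation (id, genotype, qualifier, term, reference
#' annotation, extensions, evidence, literature reference, conditions,
#' notes, created/modified dates) and one row per genotype (id, label,
#' genotype text, ancestry, virtual flag, source, reference, external
#' ids). Extensions render as pipe-separated `REL(T1,T2)` units and
#' conditions as pipe-separated `key=value` pairs. Rows are sorted by id,
#' empty optionals render as empty fields, and the output is
#' byte-deterministic for a given repository. Tab, pipe, comma, and
#' parenthesis characters are forbidden inside free-text field values
#' rather than escaped. The repository must first pass
#' [validate_repository()] with zero error-severity findings.
#'
#' @param repo An [omp_repository()].
#' @param ontologies Passed to [validate_repository()]; set `validate =
#'   FALSE` to skip the gate (e.g. for already-validated repositories).
#' @param config An [omp_config()].
#' @param validate Logical; validate before writing (default `TRUE` when
#'   `ontologies` is given).
#' @return A list with `annotation_tsv` and `genotype_tsv`, each a single
#'   string.
#' @seealso [read_release()], [write_json()]
#' @export
write_release <- function(repo, ontologies = NULL, config = omp_config(),
                          validate = !is.null(ontologies)) {
  stopifnot(inherits(repo, "omp_repository"))
  if (validate) {
    v <- validate_repository(repo, ontologies, config)
    errs <- v[v$severity == "error", , drop = FALSE]
    if (nrow(errs)) {
      stop("repository fails validation with ", nrow(errs), " error(s): ",
           paste(unique(paste0(errs$rule_id, " ", errs$annotation_id)),
                 collapse = "; "), call. = FALSE)
    }
  }
  ann_rows <- vapply(radix_sort(names(repo$annotations)), function(id) {
    a <- repo$annotations[[id]]
    for (f in c("notes", "reference")) {
      if (!is.null(a[[f]])) check_field_chars(a[[f]], paste0(id, " ", f))
    }
    if (nrow(a$conditions)) {
      apply(a$conditions, 1L, function(r) check_field_chars(r[["value"]], paste0(id, " conditions")))
    }
    paste(c(a$annotation_id, a$genotype_id, opt(a$qualifier), a$omp_term_id,
            opt(a$relative_to), render_extensions(a$extensions), a$eco_id,
            a$reference, render_conditions(a$conditions), opt(a$notes),
            a$history[[1L]]$timestamp,
            a$history[[length(a$history)]]$timestamp),
          collapse = "\t")
  }, character(1))
  geno_rows <- vapply(radix_sort(names(repo$genotypes)), function(id) {
    g <- repo$genotypes[[id]]
    for (f in c("label", "genotype_text", "source")) {
      if (!is.null(g[[f]])) check_field_chars(g[[f]], paste0(id, " ", f))
    }
    paste(c(g$genotype_id, g$label, g$genotype_text, opt(g$ancestry),
            if (g$is_virtual) "true" else "false", opt(g$source),
            opt(g$reference), paste(g$external_ids, collapse = "|")),
          collapse = "\t")
  }, character(1))
  list(
    annotation_tsv = paste0(paste(
      c(paste0("!", paste(ANNOTATION_COLUMNS, collapse = "\t")), ann_rows),
      collapse = "\n"), "\n"),
    genotype_tsv = paste0(paste(
      c(paste0("!", paste(GENOTYPE_COLUMNS, collapse = "\t")), geno_rows),
      collapse = "\n"), "\n")
  )
}

parse_extensions <- function(cell) {
  if (!nzchar(cell)) return(list())
  units <- strsplit(cell, "|", fixed = TRUE)[[1L]]
  lapply(units, function(u) {
    m <- regmatches(u, regexec("^([^()]+)\\(([^()]+)\\)$", u))[[1L]]
    if (length(m) != 3L) stop("malformed extension cell: ", u, call. = FALSE)
    omp_extension(m[2L], strsplit(m[3L], ",", fixed = TRUE)[[1L]])
  })
}

parse_conditions_cell <- function(cell) {
  if (!nzchar(cell)) return(omp_conditions())
  pairs <- strsplit(cell, "|", fixed = TRUE)[[1L]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  conditions_from_pairs(vapply(kv, `[`, character(1), 1L),
                        vapply(kv, function(p) paste(p[-1L], collapse = "="),
                               character(1)))
}

id_integer <- function(id) {
  as.integer(sub("-.*$", "", sub("^[A-Za-z_]+:", "", id)))
}

blank_null <- function(x) if (nzchar(x)) x else NULL

#' Read the paired release files back into a repository
#'
#' Inverse of [write_release()] for all exported fields. The genotype file
#' is read first so annotation rows can be checked against it; a row whose
#' genotype does not resolve, or with the wrong column count, is an error
#' naming the line. Full history event lists are not round-tripped: each
#' annotation's history collapses to a "created" event at `created_date`
#' plus, when `modified_date` differs, a "revised" event. Identifier
#' counters resume past the largest imported id.
#'
#' @param annotation_tsv,genotype_tsv File contents as single strings (or
#'   character vectors of lines).
#' @return An [omp_repository()].
#' @export
read_release <- function(annotation_tsv, genotype_tsv) {
  repo <- omp_repository()
  split_rows <- function(txt) {
    lines <- if (length(txt) == 1L) strsplit(txt, "\n", fixed = TRUE)[[1L]] else txt
    keep <- nzchar(lines) & !startsWith(lines, "!")
    list(rows = lines[keep], line_no = which(keep))
  }

  g <- split_rows(genotype_tsv)
  for (i in seq_along(g$rows)) {
    f <- strsplit(g$rows[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) > length(GENOTYPE_COLUMNS) || length(f) < 3L) {
      stop("genotype file line ", g$line_no[i], ": expected ",
           length(GENOTYPE_COLUMNS), " columns, found ", length(f),
           call. = FALSE)
    }
    length(f) <- length(GENOTYPE_COLUMNS)  # pad trailing empties
    f[is.na(f)] <- ""
    if (!grepl(GENOTYPE_ID_RE, f[1L])) {
      stop("genotype file line ", g$line_no[i], ": bad genotype id ", f[1L],
           call. = FALSE)
    }
    geno <- structure(
      list(genotype_id = f[1L], label = f[2L], genotype_text = f[3L],
           ancestry = blank_null(f[4L]), source = blank_null(f[6L]),
           reference = blank_null(f[7L]),
           external_ids = if (nzchar(f[8L])) strsplit(f[8L], "|", fixed = TRUE)[[1L]] else character(),
           is_virtual = identical(f[5L], "true")),
      class = "omp_genotype"
    )
    if (!is.null(repo$genotypes[[geno$genotype_id]])) {
      stop("genotype file line ", g$line_no[i], ": duplicate id ",
           geno$genotype_id, call. = FALSE)
    }
    repo$genotypes[[geno$genotype_id]] <- geno
  }

  a <- split_rows(annotation_tsv)
  for (i in seq_along(a$rows)) {
    f <- strsplit(a$rows[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(ANNOTATION_COLUMNS)) {
      stop("annotation file line ", a$line_no[i], ": expected ",
           length(ANNOTATION_COLUMNS), " columns, found ", length(f),
           call. = FALSE)
    }
    if (!grepl(ANNOTATION_ID_RE, f[1L])) {
      stop("annotation file line ", a$line_no[i], ": bad annotation id ",
           f[1L], call. = FALSE)
    }
    if (is.null(repo$genotypes[[f[2L]]])) {
      stop("annotation file line ", a$line_no[i], ": genotype ", f[2L],
           " not in genotype file", call. = FALSE)
    }
    history <- list(history_event(f[11L], "import", "created"))
    if (nzchar(f[12L]) && !identical(f[12L], f[11L])) {
      history[[2L]] <- history_event(f[12L], "import", "revised")
    }
    ann <- structure(
      list(annotation_id = f[1L], genotype_id = f[2L],
           conditions = parse_conditions_cell(f[9L]), omp_term_id = f[4L],
           extensions = parse_extensions(f[6L]),
           relative_to = blank_null(f[5L]), qualifier = blank_null(f[3L]),
           eco_id = f[7L], reference = f[8L], history = history,
           notes = blank_null(f[10L])),
      class = "omp_annotation"
    )
    if (!is.null(repo$annotations[[ann$annotation_id]])) {
      stop("annotation file line ", a$line_no[i], ": duplicate id ",
           ann$annotation_id, call. = FALSE)
    }
    repo$annotations[[ann$annotation_id]] <- ann
  }

  if (length(repo$genotypes)) {
    repo$next_genotype <- max(vapply(names(repo$genotypes), id_integer, integer(1))) + 1L
  }
  if (length(repo$annotations)) {
    repo$next_annotation <- max(vapply(names(repo$annotations), id_integer, integer(1))) + 1L
  }
  repo
}

annotation_to_list <- function(a) {
  list(
    annotation_id = a$annotation_id,
    genotype_id = a$genotype_id,
    conditions = lapply(seq_len(nrow(a$conditions)), function(i) {
      list(key = a$conditions$key[i], value = a$conditions$value[i])
    }),
    omp_term_id = a$omp_term_id,
    extensions = lapply(a$extensions, function(e) {
      list(relation_id = e$relation_id, target_ids = as.list(e$target_ids))
    }),
    relative_to = a$relative_to,
    qualifier = a$qualifier,
    eco_id = a$eco_id,
    reference = a$reference,
    history = lapply(a$history, function(h) {
      list(timestamp = h$timestamp, editor = h$editor, action = h$action,
           note = h$note)
    }),
    notes = a$notes
  )
}

genotype_to_list <- function(g) {
  list(genotype_id = g$genotype_id, label = g$label,
       genotype_text = g$genotype_text, ancestry = g$ancestry,
       source = g$source, reference = g$reference,
       external_ids = as.list(g$external_ids), is_virtual = g$is_virtual)
}

#' Export the repository as a JSON document
#'
#' One document with top-level keys `genotypes` and `annotations`, every
#' field of both record types serialized — including full history event
#' lists, which the tab-delimited export collapses — with stable key
#' order. The output conforms to the schema shipped at
#' `system.file("schema", "release-schema.json", package = "ompannot")`;
#' see [validate_release_json()].
#'
#' @inheritParams write_release
#' @return JSON text (a single string).
#' @export
write_json <- function(repo, ontologies = NULL, config = omp_config(),
                       validate = !is.null(ontologies)) {
  stopifnot(inherits(repo, "omp_repository"))
  if (validate) {
    v <- validate_repository(repo, ontologies, config)
    errs <- v[v$severity == "error", , drop = FALSE]
    if (nrow(errs)) {
      stop("repository fails validation with ", nrow(errs), " error(s)",
           call. = FALSE)
    }
  }
  doc <- list(
    format = "omp-annotation-release",
    genotypes = lapply(radix_sort(names(repo$genotypes)),
                       function(id) genotype_to_list(repo$genotypes[[id]])),
    annotations = lapply(radix_sort(names(repo$annotations)),
                         function(id) annotation_to_list(repo$annotations[[id]]))
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE)
}

#' Read a JSON export back into a repository
#'
#' Lossless inverse of [write_json()]: full history event lists are
#' restored.
#'
#' @param json_text JSON document as a string.
#' @return An [omp_repository()].
#' @export
read_json <- function(json_text) {
  doc <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  repo <- omp_repository()
  for (g in doc$genotypes) {
    geno <- structure(
      list(genotype_id = g$genotype_id, label = g$label,
           genotype_text = g$genotype_text, ancestry = g$ancestry,
           source = g$source, reference = g$reference,
           external_ids = as.character(unlist(g$external_ids)),
           is_virtual = isTRUE(g$is_virtual)),
      class = "omp_genotype"
    )
    repo$genotypes[[geno$genotype_id]] <- geno
  }
  for (a in doc$annotations) {
    ann <- structure(
      list(
        annotation_id = a$annotation_id, genotype_id = a$genotype_id,
        conditions = if (length(a$conditions)) {
          conditions_from_pairs(vapply(a$conditions, `[[`, character(1), "key"),
                                vapply(a$conditions, `[[`, character(1), "value"))
        } else omp_conditions(),
        omp_term_id = a$omp_term_id,
        extensions = lapply(a$extensions, function(e) {
          omp_extension(e$relation_id, as.character(unlist(e$target_ids)))
        }),
        relative_to = a$relative_to, qualifier = a$qualifier,
        eco_id = a$eco_id, reference = a$reference,
        history = lapply(a$history, function(h) {
          history_event(h$timestamp, h$editor, h$action, h$note)
        }),
        notes = a$notes),
      class = "omp_annotation"
    )
    repo$annotations[[ann$annotation_id]] <- ann
  }
  if (length(repo$genotypes)) {
    repo$next_genotype <- max(vapply(names(repo$genotypes), id_integer, integer(1))) + 1L
  }
  if (length(repo$annotations)) {
    repo$next_annotation <- max(vapply(names(repo$annotations), id_integer, integer(1))) + 1L
  }
  repo
}
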
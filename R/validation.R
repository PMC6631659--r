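## Validation engine: enforce the annotation standard's rules at the
## annotation and repository level. Findings are returned as a violations
## table, never thrown.

REFERENCE_RE <- "^[A-Za-z]+:[A-Za-z0-9.]+$"

violation <- function(rule_id, annotation_id, message, severity = "error") {
  data.frame(rule_id = rule_id, annotation_id = annotation_id,
             message = message, severity = severity, stringsAsFactors = FALSE)
}

empty_violations <- function() {
  structure(
    data.frame(rule_id = character(), annotation_id = character(),
               message = character(), severity = character(),
               stringsAsFactors = FALSE),
    class = c("omp_violations", "data.frame")
  )
}

finish_violations <- function(vs) {
  out <- do.call(rbind, c(list(empty_violations()), vs))
  out <- out[order(out$annotation_id, out$rule_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("omp_violations", "data.frame"))
}

#' Validate one annotation against the annotation standard
#'
#' Applies all rules and returns every violation found (never just the
#' first). The rules, with their ids:
#'
#' * **R1** the phenotype term exists in the phenotype ontology and is not
#'   obsolete.
#' * **R2** the evidence term exists in the evidence ontology and is not
#'   obsolete.
#' * **R3** a dependent phenotype term (see [is_dependent_term()]) requires
#'   `relative_to`.
#' * **R4** `relative_to`, when set, resolves in the repository and
#'   introduces no reference cycle.
#' * **R5** the qualifier, when set, is one of the three allowed values
#'   ([omp_qualifiers()]).
#' * **R6** "Same phenotype as reference strain" requires a `relative_to`
#'   annotation with a *different* genotype (the claim is that a genotype
#'   change leaves the phenotype unchanged).
#' * **R7** "Same phenotype as in reference condition" requires a
#'   `relative_to` annotation with the *same* genotype and different
#'   conditions (the claim is about an environment change).
#' * **R8** every extension pairs a well-formed relation CURIE with at
#'   least one well-formed target CURIE.
#' * **R9** the literature reference is a CURIE; a non-`PMID` prefix is a
#'   warning, not an error.
#' * **R10** condition keys come from the allowed set and `ENVO` values
#'   are ENVO CURIEs.
#'
#' Genotype-id comparisons (R6/R7) use id equality, not genotype-text
#' similarity: isogenicity is not computable from the recorded fields.
#' Obsolete-term use is an error, reflecting a curation-quality stance.
#'
#' @param ann An `omp_annotation`.
#' @param repo The [omp_repository()] holding it (for reference checks).
#' @param ontologies Named list with elements `omp` and `eco`, each an
#'   `omp_ontology`.
#' @param config An [omp_config()] controlling dependent-term detection.
#' @return An `omp_violations` data frame (columns `rule_id`,
#'   `annotation_id`, `message`, `severity`), ordered by
#'   (annotation_id, rule_id); zero rows when the annotation is clean.
#' @export
validate_annotation <- function(ann, repo, ontologies, config = omp_config()) {
  vs <- list()
  aid <- ann$annotation_id
  add <- function(rule, msg, severity = "error") {
    vs[[length(vs) + 1L]] <<- violation(rule, aid, msg, severity)
  }

  omp_ont <- ontologies$omp
  eco_ont <- ontologies$eco

  ## R1: phenotype term exists and is current
  term <- lookup_term(omp_ont, ann$omp_term_id)
  if (is.null(term)) {
    add("R1", paste0("phenotype term ", ann$omp_term_id, " not in ontology"))
  } else if (term$is_obsolete) {
    add("R1", paste0("phenotype term ", ann$omp_term_id, " is obsolete"))
  }

  ## R2: evidence term exists and is current
  eterm <- lookup_term(eco_ont, ann$eco_id)
  if (is.null(eterm)) {
    add("R2", paste0("evidence term ", ann$eco_id, " not in ontology"))
  } else if (eterm$is_obsolete) {
    add("R2", paste0("evidence term ", ann$eco_id, " is obsolete"))
  }

  ## R3: dependent phenotype needs a reference annotation
  if (!is.null(term) && !term$is_obsolete &&
      is_dependent_term(omp_ont, ann$omp_term_id, config) &&
      is.null(ann$relative_to)) {
    add("R3", paste0("dependent phenotype ", ann$omp_term_id,
                     " requires relative_to"))
  }

  ## R4: relative_to resolves, no cycle
  ref <- NULL
  if (!is.null(ann$relative_to)) {
    ref <- repo$annotations[[ann$relative_to]]
    if (is.null(ref)) {
      add("R4", paste0("relative_to ", ann$relative_to, " does not resolve"))
    } else {
      cyc <- tryCatch({ check_relative_to_acyclic(repo, ann); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(cyc)) add("R4", cyc)
    }
  }

  ## R5: qualifier from the closed set
  if (!is.null(ann$qualifier) && !(ann$qualifier %in% QUALIFIERS)) {
    add("R5", paste0("qualifier \"", ann$qualifier, "\" not one of: ",
                     paste(QUALIFIERS, collapse = "; ")))
  }

  ## R6 / R7: qualifier semantics against the reference annotation
  if (identical(ann$qualifier, "Same phenotype as reference strain")) {
    if (is.null(ref)) {
      add("R6", "qualifier requires a resolvable relative_to annotation")
    } else if (identical(ref$genotype_id, ann$genotype_id)) {
      add("R6", "reference annotation must have a different genotype")
    }
  }
  if (identical(ann$qualifier, "Same phenotype as in reference condition")) {
    if (is.null(ref)) {
      add("R7", "qualifier requires a resolvable relative_to annotation")
    } else if (!identical(ref$genotype_id, ann$genotype_id)) {
      add("R7", "reference annotation must have the same genotype")
    } else if (identical(render_conditions(ref$conditions),
                         render_conditions(ann$conditions))) {
      add("R7", "reference annotation must have different conditions")
    }
  }

  ## R8: extension well-formedness
  for (e in ann$extensions) {
    ok_rel <- grepl(CURIE_RE, e$relation_id)
    ok_targets <- length(e$target_ids) >= 1L && all(grepl(CURIE_RE, e$target_ids))
    if (!ok_rel || !ok_targets) {
      add("R8", paste0("malformed extension ", render_extensions(list(e))))
    }
  }

  ## R9: reference CURIE shape; non-PMID prefix is only a warning
  if (is.null(ann$reference) || !grepl(REFERENCE_RE, ann$reference)) {
    add("R9", paste0("reference \"",
                     if (is.null(ann$reference)) "" else ann$reference,
                     "\" is not a CURIE"))
  } else if (!startsWith(ann$reference, "PMID:")) {
    add("R9", paste0("reference prefix is not PMID: ", ann$reference),
        severity = "warning")
  }

  ## R10: condition keys and ENVO value shape
  if (nrow(ann$conditions)) {
    bad_keys <- setdiff(unique(ann$conditions$key), CONDITION_KEYS)
    if (length(bad_keys)) {
      add("R10", paste0("condition key(s) not allowed: ",
                        paste(bad_keys, collapse = ", ")))
    }
    envo <- ann$conditions$value[ann$conditions$key == "ENVO"]
    bad_envo <- envo[!grepl("^ENVO:[0-9]+$", envo)]
    if (length(bad_envo)) {
      add("R10", paste0("ENVO condition value(s) not ENVO CURIEs: ",
                        paste(bad_envo, collapse = ", ")))
    }
  }

  finish_violations(vs)
}

#' Validate a whole repository
#'
#' Runs [validate_annotation()] on every annotation and adds
#' repository-level checks: dangling genotype references (`G1`, e.g. after
#' a tombstoned deletion), duplicate identifiers (`G2`), `relative_to`
#' cycles (`R4`, naming every annotation on the cycle), and — as a warning
#' (`V1`) — annotations on virtual strains that sit on a qualifier-free
#' dependent comparison chain longer than two links, where the averaged
#' reference makes long unqualified chains hard to interpret.
#'
#' @inheritParams validate_annotation
#' @param repo An [omp_repository()].
#' @return An `omp_violations` data frame; repository-level findings carry
#'   the affected id in `annotation_id` (or `"<repository>"`).
#' @export
validate_repository <- function(repo, ontologies, config = omp_config()) {
  vs <- list()
  for (ann in repo$annotations) {
    v <- validate_annotation(ann, repo, ontologies, config)
    if (nrow(v)) vs[[length(vs) + 1L]] <- v
  }
  ## G1: dangling genotype references
  for (ann in repo$annotations) {
    if (is.null(repo$genotypes[[ann$genotype_id]])) {
      vs[[length(vs) + 1L]] <- violation(
        "G1", ann$annotation_id,
        paste0("genotype ", ann$genotype_id, " does not resolve",
               if (ann$genotype_id %in% repo$tombstones) " (deleted)" else ""))
    }
  }
  ## G1: dangling ancestry
  for (g in repo$genotypes) {
    if (!is.null(g$ancestry) && is.null(repo$genotypes[[g$ancestry]])) {
      vs[[length(vs) + 1L]] <- violation(
        "G1", g$genotype_id,
        paste0("ancestry ", g$ancestry, " does not resolve"))
    }
  }
  ## G2: duplicate ids (defensive; the constructors forbid them)
  all_ids <- c(names(repo$genotypes), names(repo$annotations))
  dups <- unique(all_ids[duplicated(all_ids)])
  for (d in dups) {
    vs[[length(vs) + 1L]] <- violation("G2", d, paste0("duplicate id ", d))
  }
  ## R4: relative_to cycles, naming each participant
  on_cycle <- find_relative_to_cycles(repo)
  for (aid in on_cycle) {
    vs[[length(vs) + 1L]] <- violation(
      "R4", aid, paste0("relative_to cycle through ",
                        paste(on_cycle, collapse = ", ")))
  }
  ## V1: virtual strains with long unqualified dependent chains
  for (ann in repo$annotations) {
    g <- repo$genotypes[[ann$genotype_id]]
    if (is.null(g) || !g$is_virtual || !is.null(ann$qualifier)) next
    len <- chain_length(repo, ann)
    if (len > 2L) {
      vs[[length(vs) + 1L]] <- violation(
        "V1", ann$annotation_id,
        paste0("virtual strain ", g$genotype_id,
               " carries a qualifier-free dependent chain of length ", len),
        severity = "warning")
    }
  }
  finish_violations(vs)
}

find_relative_to_cycles <- function(repo) {
  on_cycle <- character()
  for (ann in repo$annotations) {
    seen <- character()
    cur <- ann
    repeat {
      if (is.null(cur$relative_to)) break
      if (cur$relative_to %in% c(seen, ann$annotation_id)) {
        on_cycle <- union(on_cycle, c(seen, ann$annotation_id, cur$relative_to))
        break
      }
      seen <- c(seen, cur$relative_to)
      cur <- repo$annotations[[cur$relative_to]]
      if (is.null(cur)) break
    }
  }
  sort(on_cycle)
}

chain_length <- function(repo, ann) {
  len <- 0L
  seen <- character()
  cur <- ann
  while (!is.null(cur$relative_to) && !(cur$relative_to %in% seen)) {
    len <- len + 1L
    seen <- c(seen, cur$relative_to)
    cur <- repo$annotations[[cur$relative_to]]
    if (is.null(cur)) break
  }
  len
}

#' @export
print.omp_violations <- function(x, ...) {
  if (!nrow(x)) {
    cat("no violations\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("[%s] %-7s %s: %s\n", x$severity[i], x$rule_id[i],
                x$annotation_id[i], x$message[i]))
  }
  invisible(x)
}
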
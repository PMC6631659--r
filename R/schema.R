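## Structural validation of the JSON export against the shipped schema
## document. Covers the JSON-Schema keywords the schema uses: type,
## required, properties, items, enum, pattern.

#' Validate a JSON release document against the shipped schema
#'
#' Checks [write_json()] output against the schema document shipped at
#' `inst/schema/release-schema.json` (keywords: `type`, `required`,
#' `properties`, `items`, `enum`, `pattern`).
#'
#' @param json_text JSON document as a string.
#' @param schema_path Path to a JSON-Schema document; defaults to the
#'   shipped release schema.
#' @return Character vector of violation messages with JSON-pointer-style
#'   paths; length zero when the document conforms.
#' @export
validate_release_json <- function(json_text,
                                  schema_path = system.file("schema",
                                                            "release-schema.json",
                                                            package = "ompannot")) {
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  doc <- jsonlite::fromJSON(json_text, simplifyVector = FALSE)
  check_schema_node(doc, schema, "$")
}

json_type <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) return("object")
    if (length(x) == 0L) return("array")  # empty containers read as arrays
    return("array")
  }
  if (is.character(x)) return("string")
  if (is.logical(x)) return("boolean")
  if (is.numeric(x)) return("number")
  "unknown"
}

check_schema_node <- function(x, schema, path) {
  msgs <- character()
  types <- schema$type
  if (!is.null(types)) {
    allowed <- as.character(unlist(types))
    actual <- json_type(x)
    ## an empty named list is an ambiguous object/array in R
    if (!(actual %in% allowed) &&
        !(actual == "array" && "object" %in% allowed && length(x) == 0L)) {
      return(paste0(path, ": expected type ", paste(allowed, collapse = "|"),
                    ", got ", actual))
    }
    if (actual == "null") return(msgs)
  }
  if (!is.null(schema$enum)) {
    allowed <- lapply(schema$enum, identity)
    hit <- any(vapply(allowed, function(v) identical(v, x) ||
                        (is.null(v) && is.null(x)), logical(1)))
    if (!hit) {
      msgs <- c(msgs, paste0(path, ": value ", deparse(x),
                             " not in the allowed set"))
    }
  }
  if (!is.null(schema$pattern) && is.character(x)) {
    if (!grepl(schema$pattern, x, perl = TRUE)) {
      msgs <- c(msgs, paste0(path, ": \"", x, "\" does not match ",
                             schema$pattern))
    }
  }
  if (json_type(x) == "object") {
    for (req in as.character(unlist(schema$required))) {
      if (!(req %in% names(x))) {
        msgs <- c(msgs, paste0(path, ": missing required key \"", req, "\""))
      }
    }
    for (key in names(schema$properties)) {
      if (key %in% names(x)) {
        msgs <- c(msgs, check_schema_node(x[[key]], schema$properties[[key]],
                                          paste0(path, ".", key)))
      }
    }
  }
  if (json_type(x) == "array" && !is.null(schema$items)) {
    for (i in seq_along(x)) {
      msgs <- c(msgs, check_schema_node(x[[i]], schema$items,
                                        paste0(path, "[", i, "]")))
    }
  }
  msgs
}
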
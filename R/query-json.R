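# JSON (de)serialization of Structured Queries.
#
# Parsing is strict: unknown object fields are rejected with a diagnostic
# naming the JSON path, so drift between query dialects surfaces early
# instead of silently dropping a restriction (which would inflate cohorts).

check_fields <- function(obj, allowed, path) {
  if (!is.list(obj) || is.null(names(obj)) && length(obj) > 0L)
    fq_abort("fq_validation_error", sprintf("expected a JSON object at %s", path))
  unknown <- setdiff(names(obj), allowed)
  if (length(unknown))
    fq_abort("fq_validation_error",
             sprintf("unknown field '%s' at %s", unknown[[1]], path),
             field = paste0(path, ".", unknown[[1]]))
}

term_code_from_list <- function(x, path) {
  check_fields(x, c("system", "code", "display"), path)
  term_code(x$system %||% "", x$code %||% "", x$display)
}

value_filter_from_list <- function(x, path) {
  check_fields(x, c("type", "selectedConcepts", "comparator", "value",
                    "minValue", "maxValue", "unit"), path)
  kind <- x$type
  if (!is_string(kind))
    fq_abort("fq_validation_error", sprintf("valueFilter at %s lacks 'type'", path))
  sel <- NULL
  if (!is.null(x$selectedConcepts))
    sel <- lapply(seq_along(x$selectedConcepts), function(i)
      term_code_from_list(x$selectedConcepts[[i]],
                          sprintf("%s.selectedConcepts[%d]", path, i)))
  value_filter(kind, selectedConcepts = sel, comparator = x$comparator,
               value = x$value, minValue = x$minValue, maxValue = x$maxValue,
               unit = x$unit)
}

time_restriction_from_list <- function(x, path) {
  check_fields(x, c("afterDate", "beforeDate"), path)
  time_restriction(afterDate = x$afterDate, beforeDate = x$beforeDate)
}

criterion_from_list <- function(x, path) {
  check_fields(x, c("termCodes", "valueFilter", "timeRestriction"), path)
  if (is.null(x$termCodes) || length(x$termCodes) == 0L)
    fq_abort("fq_validation_error",
             sprintf("criterion at %s requires non-empty 'termCodes'", path))
  tcs <- lapply(seq_along(x$termCodes), function(i)
    term_code_from_list(x$termCodes[[i]], sprintf("%s.termCodes[%d]", path, i)))
  vf <- if (!is.null(x$valueFilter))
    value_filter_from_list(x$valueFilter, paste0(path, ".valueFilter"))
  tr <- if (!is.null(x$timeRestriction))
    time_restriction_from_list(x$timeRestriction, paste0(path, ".timeRestriction"))
  criterion(tcs, valueFilter = vf, timeRestriction = tr)
}

groups_from_list <- function(x, path) {
  lapply(seq_along(x), function(i) {
    g <- x[[i]]
    if (!is.list(g) || length(g) == 0L || !is.null(names(g)))
      fq_abort("fq_validation_error",
               sprintf("group at %s[%d] must be a non-empty JSON array", path, i))
    lapply(seq_along(g), function(j)
      criterion_from_list(g[[j]], sprintf("%s[%d][%d]", path, i, j)))
  })
}

#' Parse a Structured Query JSON document
#'
#' Reads the JSON dialect with top-level keys `version`,
#' `inclusionCriteria`, `exclusionCriteria`; criterion keys `termCodes`,
#' `valueFilter`, `timeRestriction`. All invariants of the query model are
#' validated and unknown fields anywhere in the document are rejected with
#' a diagnostic naming the field path. A JSON Schema for the dialect ships
#' at `system.file("extdata", "structured-query.schema.json",
#' package = "feasquery")`.
#'
#' @param text JSON text (or a connection/path accepted by
#'   [jsonlite::fromJSON()] when `is_file = TRUE`).
#' @param is_file interpret `text` as a file path.
#' @return A validated [structured_query()].
#' @export
parse_structured_query <- function(text, is_file = FALSE) {
  if (is_file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(
    jsonlite::parse_json(text),
    error = function(e)
      fq_abort("fq_parse_error", paste0("malformed JSON: ", conditionMessage(e))))
  check_fields(doc, c("version", "inclusionCriteria", "exclusionCriteria"), "$")
  if (is.null(doc$inclusionCriteria) || length(doc$inclusionCriteria) == 0L)
    fq_abort("fq_validation_error", "inclusionCriteria is missing or empty")
  structured_query(
    inclusionCriteria = groups_from_list(doc$inclusionCriteria, "$.inclusionCriteria"),
    exclusionCriteria = groups_from_list(doc$exclusionCriteria %||% list(),
                                         "$.exclusionCriteria"),
    version = doc$version %||% "fq/v1")
}

term_code_to_list <- function(tc) {
  out <- list(system = tc$system, code = tc$code)
  if (!is.null(tc$display)) out$display <- tc$display
  out
}

value_filter_to_list <- function(vf) {
  out <- list(type = vf$kind)
  if (vf$kind == "concept") {
    out$selectedConcepts <- lapply(vf$selectedConcepts, term_code_to_list)
  } else if (vf$kind == "quantity-comparator") {
    out$comparator <- vf$comparator; out$value <- vf$value; out$unit <- vf$unit
  } else {
    out$minValue <- vf$minValue; out$maxValue <- vf$maxValue; out$unit <- vf$unit
  }
  out
}

criterion_to_list <- function(cr) {
  out <- list(termCodes = lapply(cr$termCodes, term_code_to_list))
  if (!is.null(cr$valueFilter)) out$valueFilter <- value_filter_to_list(cr$valueFilter)
  if (!is.null(cr$timeRestriction)) {
    tr <- list()
    if (!is.null(cr$timeRestriction$afterDate))
      tr$afterDate <- cr$timeRestriction$afterDate
    if (!is.null(cr$timeRestriction$beforeDate))
      tr$beforeDate <- cr$timeRestriction$beforeDate
    out$timeRestriction <- tr
  }
  out
}

#' Serialize a Structured Query to canonical JSON
#'
#' Key order is fixed (version, inclusionCriteria, exclusionCriteria; within
#' a criterion: termCodes, valueFilter, timeRestriction), so serialization
#' is deterministic and byte-identical across runs for equal inputs.
#' `parse_structured_query(serialize_structured_query(q))` reproduces `q`.
#'
#' @param q an [structured_query()].
#' @param pretty pretty-print the JSON.
#' @return A single string of JSON text.
#' @export
serialize_structured_query <- function(q, pretty = FALSE) {
  stopifnot(inherits(q, "fq_structured_query"))
  doc <- list(
    version = q$version,
    inclusionCriteria = lapply(q$inclusionCriteria, function(g)
      lapply(g, criterion_to_list)),
    exclusionCriteria = lapply(q$exclusionCriteria, function(g)
      lapply(g, criterion_to_list)))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = pretty))
}
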
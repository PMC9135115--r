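#' Term codes
#'
#' A term code is a (code system, code) pair uniquely identifying a medical
#' concept within a vocabulary such as ICD-10-GM, OPS or LOINC, together with
#' an optional human-readable display string. Equality of term codes is by
#' `(system, code)` only; the display never takes part in comparisons.
#'
#' @param system code system URI, e.g. `"http://loinc.org"`. Non-empty.
#' @param code concept code within the system. Non-empty.
#' @param display optional human-readable label.
#' @return An object of class `fq_term_code`.
#' @examples
#' term_code("http://loinc.org", "55782-7", "HER2 panel")
#' @export
term_code <- function(system, code, display = NULL) {
  if (!is_nonempty_string(system))
    fq_abort("fq_validation_error", "term code 'system' must be a non-empty string")
  if (!is_nonempty_string(code))
    fq_abort("fq_validation_error", "term code 'code' must be a non-empty string")
  if (!is.null(display) && !is_string(display))
    fq_abort("fq_validation_error", "term code 'display' must be a string if present")
  structure(list(system = system, code = code, display = display),
            class = "fq_term_code")
}

#' Identity key of a term code: system and code, display ignored.
#' @param tc an `fq_term_code`.
#' @return A single string `system|code`.
#' @export
term_code_key <- function(tc) paste0(tc$system, "|", tc$code)

term_code_equal <- function(a, b) {
  identical(a$system, b$system) && identical(a$code, b$code)
}

#' @export
print.fq_term_code <- function(x, ...) {
  cat(sprintf("<term code> %s|%s%s\n", x$system, x$code,
              if (!is.null(x$display)) paste0(" (", x$display, ")") else ""))
  invisible(x)
}

#' Value filters
#'
#' Restricts a criterion to resources with a particular coded or measured
#' value: `concept` selects resources whose value is one of a set of codes,
#' `quantity-comparator` compares a numeric value against a threshold, and
#' `quantity-range` bounds it on both sides. Units are UCUM codes.
#'
#' @param kind one of `"concept"`, `"quantity-comparator"`, `"quantity-range"`.
#' @param selectedConcepts list of [term_code()] (concept kind only).
#' @param comparator one of gt, ge, lt, le, eq (quantity-comparator only).
#' @param value numeric threshold (quantity-comparator only).
#' @param minValue,maxValue numeric bounds (quantity-range only).
#' @param unit UCUM unit code (quantity kinds only).
#' @return An object of class `fq_value_filter`.
#' @export
value_filter <- function(kind, selectedConcepts = NULL, comparator = NULL,
                         value = NULL, minValue = NULL, maxValue = NULL,
                         unit = NULL) {
  kinds <- c("concept", "quantity-comparator", "quantity-range")
  if (!is_string(kind) || !kind %in% kinds)
    fq_abort("fq_validation_error",
             sprintf("unknown valueFilter kind %s", deparse(kind)))
  chk_absent <- function(name, val) {
    if (!is.null(val))
      fq_abort("fq_validation_error",
               sprintf("valueFilter field '%s' not allowed for kind '%s'", name, kind))
  }
  if (kind == "concept") {
    chk_absent("comparator", comparator); chk_absent("value", value)
    chk_absent("minValue", minValue); chk_absent("maxValue", maxValue)
    chk_absent("unit", unit)
    if (!is.list(selectedConcepts) || length(selectedConcepts) == 0L)
      fq_abort("fq_validation_error",
               "concept valueFilter requires non-empty 'selectedConcepts'")
    if (!all(vapply(selectedConcepts, inherits, logical(1), "fq_term_code")))
      fq_abort("fq_validation_error", "'selectedConcepts' must contain term codes")
  } else if (kind == "quantity-comparator") {
    chk_absent("selectedConcepts", selectedConcepts)
    chk_absent("minValue", minValue); chk_absent("maxValue", maxValue)
    if (!is_string(comparator) || !comparator %in% c("gt", "ge", "lt", "le", "eq"))
      fq_abort("fq_validation_error",
               "comparator must be one of gt, ge, lt, le, eq")
    if (!is.numeric(value) || length(value) != 1L || is.na(value))
      fq_abort("fq_validation_error", "quantity-comparator requires numeric 'value'")
    if (!is_nonempty_string(unit))
      fq_abort("fq_validation_error", "quantity valueFilter requires a UCUM 'unit'")
  } else { # quantity-range
    chk_absent("selectedConcepts", selectedConcepts)
    chk_absent("comparator", comparator); chk_absent("value", value)
    ok_num <- function(v) is.numeric(v) && length(v) == 1L && !is.na(v)
    if (!ok_num(minValue) || !ok_num(maxValue))
      fq_abort("fq_validation_error", "quantity-range requires numeric min/max")
    if (minValue > maxValue)
      fq_abort("fq_validation_error", "quantity-range requires minValue <= maxValue")
    if (!is_nonempty_string(unit))
      fq_abort("fq_validation_error", "quantity valueFilter requires a UCUM 'unit'")
  }
  # numerics normalized to double so JSON round-trips preserve identity
  structure(list(kind = kind, selectedConcepts = selectedConcepts,
                 comparator = comparator,
                 value = if (!is.null(value)) as.numeric(value),
                 minValue = if (!is.null(minValue)) as.numeric(minValue),
                 maxValue = if (!is.null(maxValue)) as.numeric(maxValue),
                 unit = unit),
            class = "fq_value_filter")
}

#' Time restrictions
#'
#' Restricts a criterion to resources whose clinical date falls within a
#' calendar-date window. Bounds are inclusive; at least one bound must be
#' present. Dates carry no time of day.
#'
#' @param afterDate,beforeDate ISO-8601 dates (`"YYYY-MM-DD"`) or `NULL`.
#' @return An object of class `fq_time_restriction`.
#' @export
time_restriction <- function(afterDate = NULL, beforeDate = NULL) {
  if (is.null(afterDate) && is.null(beforeDate))
    fq_abort("fq_validation_error", "timeRestriction requires at least one bound")
  for (d in list(afterDate, beforeDate))
    if (!is.null(d) && !is_iso_date(d))
      fq_abort("fq_validation_error",
               sprintf("timeRestriction dates must be ISO-8601 calendar dates, got %s",
                       deparse(d)))
  if (!is.null(afterDate) && !is.null(beforeDate) &&
      as.Date(afterDate) > as.Date(beforeDate))
    fq_abort("fq_validation_error", "timeRestriction requires afterDate <= beforeDate")
  structure(list(afterDate = afterDate, beforeDate = beforeDate),
            class = "fq_time_restriction")
}

#' Criteria
#'
#' One selectable concept within a feasibility query: a non-empty list of
#' term codes naming the same concept in alternative vocabularies, plus an
#' optional value filter and time restriction.
#'
#' @param termCodes a single [term_code()] or non-empty list of them.
#' @param valueFilter optional [value_filter()].
#' @param timeRestriction optional [time_restriction()].
#' @return An object of class `fq_criterion`.
#' @export
criterion <- function(termCodes, valueFilter = NULL, timeRestriction = NULL) {
  if (inherits(termCodes, "fq_term_code")) termCodes <- list(termCodes)
  if (!is.list(termCodes) || length(termCodes) == 0L ||
      !all(vapply(termCodes, inherits, logical(1), "fq_term_code")))
    fq_abort("fq_validation_error", "criterion requires a non-empty list of term codes")
  if (!is.null(valueFilter) && !inherits(valueFilter, "fq_value_filter"))
    fq_abort("fq_validation_error", "valueFilter must be created with value_filter()")
  if (!is.null(timeRestriction) && !inherits(timeRestriction, "fq_time_restriction"))
    fq_abort("fq_validation_error",
             "timeRestriction must be created with time_restriction()")
  structure(list(termCodes = termCodes, valueFilter = valueFilter,
                 timeRestriction = timeRestriction),
            class = "fq_criterion")
}

#' Canonical identity key of a criterion
#'
#' Serializes the criterion with displays stripped, yielding a string equal
#' for criteria that are equal under the query-model identity contract.
#' Used to key truth assignments in [evaluate_reference()].
#'
#' @param crit an `fq_criterion`.
#' @return A single string.
#' @export
criterion_key <- function(crit) {
  stripped <- crit
  stripped$termCodes <- lapply(crit$termCodes, function(tc)
    term_code(tc$system, tc$code))
  jsonlite::toJSON(criterion_to_list(stripped), auto_unbox = TRUE)
}

#' Structured Queries
#'
#' The formal representation of a feasibility query. Inclusion criteria are
#' a conjunctive normal form: the outer list of groups is combined by AND,
#' criteria within a group by OR. Exclusion criteria are a disjunctive
#' normal form: groups combined by OR, criteria within a group by AND. A
#' patient matches the query iff every inclusion group contains at least one
#' satisfied criterion and no exclusion group has all its criteria satisfied.
#'
#' @param inclusionCriteria non-empty list of groups; each group a non-empty
#'   list of [criterion()] objects (a single criterion is promoted to a
#'   singleton group automatically when passed bare).
#' @param exclusionCriteria possibly empty list of groups of criteria.
#' @param version dialect identifier string.
#' @return An object of class `fq_structured_query`.
#' @examples
#' diab <- criterion(term_code("http://fhir.de/CodeSystem/bfarm/icd-10-gm",
#'                             "E11", "Diabetes mellitus, Type 2"))
#' structured_query(inclusionCriteria = list(list(diab)))
#' @export
structured_query <- function(inclusionCriteria, exclusionCriteria = list(),
                             version = "fq/v1") {
  norm <- function(groups, what) {
    if (!is.list(groups))
      fq_abort("fq_validation_error", sprintf("%s must be a list of groups", what))
    lapply(groups, function(g) {
      if (inherits(g, "fq_criterion")) g <- list(g)
      if (!is.list(g) || length(g) == 0L ||
          !all(vapply(g, inherits, logical(1), "fq_criterion")))
        fq_abort("fq_validation_error",
                 sprintf("every %s group must be a non-empty list of criteria", what))
      g
    })
  }
  inclusionCriteria <- norm(inclusionCriteria, "inclusion")
  if (length(inclusionCriteria) == 0L)
    fq_abort("fq_validation_error", "inclusionCriteria must contain at least one group")
  exclusionCriteria <- norm(exclusionCriteria, "exclusion")
  if (!is_nonempty_string(version))
    fq_abort("fq_validation_error", "version must be a non-empty string")
  structure(list(version = version,
                 inclusionCriteria = inclusionCriteria,
                 exclusionCriteria = exclusionCriteria),
            class = "fq_structured_query")
}

#' @export
print.fq_structured_query <- function(x, ...) {
  cat(sprintf("<structured query> version %s\n", x$version))
  cat(sprintf("  inclusion: %d group(s) (CNF), sizes %s\n",
              length(x$inclusionCriteria),
              paste(lengths(x$inclusionCriteria), collapse = ", ")))
  if (length(x$exclusionCriteria))
    cat(sprintf("  exclusion: %d group(s) (DNF), sizes %s\n",
                length(x$exclusionCriteria),
                paste(lengths(x$exclusionCriteria), collapse = ", ")))
  else cat("  exclusion: none\n")
  invisible(x)
}

#' Structured-query equality under the identity contract
#'
#' Two queries are equal when they have the same shape and all term codes
#' agree on `(system, code)`; displays are ignored, as are value-filter and
#' time-restriction differences of representation (exact field equality).
#'
#' @param a,b `fq_structured_query` objects.
#' @return `TRUE` or `FALSE`.
#' @export
sq_equal <- function(a, b) {
  strip <- function(q) {
    q$inclusionCriteria <- lapply(q$inclusionCriteria, function(g)
      lapply(g, function(cr) { cr$termCodes <- lapply(cr$termCodes, function(tc)
        list(system = tc$system, code = tc$code)); cr }))
    q$exclusionCriteria <- lapply(q$exclusionCriteria, function(g)
      lapply(g, function(cr) { cr$termCodes <- lapply(cr$termCodes, function(tc)
        list(system = tc$system, code = tc$code)); cr }))
    q
  }
  identical(strip(a), strip(b))
}

#' All criteria of a query, in inclusion-then-exclusion document order
#' @param q an `fq_structured_query`.
#' @return List of `fq_criterion`.
#' @export
query_criteria <- function(q) {
  c(unlist(q$inclusionCriteria, recursive = FALSE),
    unlist(q$exclusionCriteria, recursive = FALSE))
}
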
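# Translation of Structured Queries into FHIR Search execution plans.
#
# FHIR Search cannot express a multi-criterion feasibility query in one
# request, so a query is broken into atomic searches (one bundle of >= 1
# searches per criterion; several searches arise when a criterion's expanded
# code list is chunked) whose patient-ID sets are recombined by set algebra.

UCUM_SYSTEM <- "http://unitsofmeasure.org"
ADMIN_GENDER_SYSTEM <- "http://hl7.org/fhir/administrative-gender"

#' Construct an atomic FHIR Search query
#'
#' @param resourceType FHIR resource type the search runs against.
#' @param parameters list of `c(name, value)` character pairs, in render
#'   order; duplicate names are allowed (FHIR ANDs repeated parameters).
#' @param sourceCriterion the [criterion()] this search implements (kept for
#'   diagnostics; not part of the rendered URL).
#' @return An object of class `fq_atomic_query`.
#' @export
atomic_query <- function(resourceType, parameters, sourceCriterion = NULL) {
  if (!is_nonempty_string(resourceType))
    fq_abort("fq_validation_error", "resourceType must be non-empty")
  ok <- all(vapply(parameters, function(p)
    is.character(p) && length(p) == 2L, logical(1)))
  if (!ok)
    fq_abort("fq_validation_error", "parameters must be (name, value) pairs")
  structure(list(resourceType = resourceType, parameters = parameters,
                 sourceCriterion = sourceCriterion),
            class = "fq_atomic_query")
}

#' Render an atomic query as a relative FHIR Search URL
#'
#' Produces `ResourceType?name=value&...`. The atomic pieces of each value
#' (systems, codes, units) are percent-encoded; the structural separators
#' `|` and `,` are emitted literally, so [parse_query_url()] recovers the
#' (resourceType, parameters) pair losslessly. Rendered URLs never contain
#' whitespace.
#'
#' @param q an [atomic_query()].
#' @return A single string.
#' @export
render_query_url <- function(q) {
  stopifnot(inherits(q, "fq_atomic_query"))
  if (length(q$parameters) == 0L) return(q$resourceType)
  parts <- vapply(q$parameters, function(p)
    paste0(p[[1]], "=", p[[2]]), character(1))
  paste0(q$resourceType, "?", paste(parts, collapse = "&"))
}

#' Parse a relative FHIR Search URL back into its components
#'
#' Inverse of [render_query_url()] over the parameter subset this package
#' emits; used by the store evaluator and in round-trip checks.
#'
#' @param url a relative search URL `Type?name=value&...`.
#' @return List with `resourceType` and `parameters` (list of name/value
#'   character pairs).
#' @export
parse_query_url <- function(url) {
  stopifnot(is_nonempty_string(url))
  qm <- regexpr("?", url, fixed = TRUE)
  if (qm == -1L) return(list(resourceType = url, parameters = list()))
  type <- substr(url, 1L, qm - 1L)
  rest <- substr(url, qm + 1L, nchar(url))
  params <- lapply(strsplit(rest, "&", fixed = TRUE)[[1]], function(p) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq == -1L)
      fq_abort("fq_parse_error", sprintf("malformed search parameter '%s'", p))
    c(substr(p, 1L, eq - 1L), substr(p, eq + 1L, nchar(p)))
  })
  list(resourceType = type, parameters = params)
}

# A token value `system|code` with both pieces percent-encoded.
render_token <- function(tc) {
  paste0(percent_encode(tc$system), "|", percent_encode(tc$code))
}

# Concept value tokens follow the FHIR convention for the administrative
# gender parameter (bare code); all other tokens are system-qualified to
# avoid cross-system code collisions.
render_concept_token <- function(tc) {
  if (identical(tc$system, ADMIN_GENDER_SYSTEM)) percent_encode(tc$code)
  else render_token(tc)
}

render_quantity <- function(prefix, value, unit) {
  paste0(prefix, format_decimal(value), "|", percent_encode(UCUM_SYSTEM), "|",
         percent_encode(unit))
}

value_filter_parameters <- function(vf, param) {
  if (vf$kind == "concept") {
    tokens <- vapply(vf$selectedConcepts, render_concept_token, character(1))
    list(c(param, paste(tokens, collapse = ",")))
  } else if (vf$kind == "quantity-comparator") {
    list(c(param, render_quantity(vf$comparator, vf$value, vf$unit)))
  } else {
    list(c(param, render_quantity("ge", vf$minValue, vf$unit)),
         c(param, render_quantity("le", vf$maxValue, vf$unit)))
  }
}

time_restriction_parameters <- function(tr, param) {
  out <- list()
  if (!is.null(tr$afterDate)) out <- c(out, list(c(param, paste0("ge", tr$afterDate))))
  if (!is.null(tr$beforeDate)) out <- c(out, list(c(param, paste0("le", tr$beforeDate))))
  out
}

#' Translate one criterion into atomic FHIR Search queries
#'
#' Every term code of the criterion is expanded through the terminology tree
#' and the union of expansions, deduplicated by `(system, code)` keeping
#' first occurrence, forms the token list on the mapping's
#' `termCodeSearchParameter`. Long code lists are split into
#' `ceiling(n / chunk_size)` queries to keep URLs bounded; the executor
#' unions their results. Value filters and time restrictions append further
#' parameters: quantity comparators render as `<cmp><value>|<system>|<unit>`,
#' ranges as a `ge`/`le` pair, concept filters as a token list, and time
#' restrictions as `ge<date>` / `le<date>` on the mapping's date parameter.
#'
#' Parameter order is deterministic: term-code parameters, then value
#' parameters, then time parameters.
#'
#' @param crit an [criterion()].
#' @param tree an `fq_term_tree`.
#' @param mapping an `fq_mapping_table`; all term codes of `crit` must
#'   resolve (error `fq_mapping_not_found` otherwise).
#' @param chunk_size maximum number of codes per query (default 200).
#' @return List of [atomic_query()]; at least one.
#' @export
criterion_to_queries <- function(crit, tree, mapping, chunk_size = 200) {
  stopifnot(inherits(crit, "fq_criterion"))
  if (!is_count(chunk_size) || chunk_size < 1)
    fq_abort("fq_validation_error", "chunk_size must be a positive integer")
  entries <- lapply(crit$termCodes, function(tc) lookup_mapping(mapping, tc))
  types <- unique(vapply(entries, `[[`, character(1), "fhirResourceType"))
  if (length(types) != 1L)
    fq_abort("fq_translation_error",
             sprintf("term codes of one criterion map to multiple resource types: %s",
                     paste(types, collapse = ", ")))
  entry <- entries[[1]]

  if (!is.null(crit$valueFilter) && is.null(entry$valueSearchParameter))
    fq_abort("fq_translation_error",
             sprintf("criterion %s has a valueFilter but its mapping lacks a valueSearchParameter",
                     term_code_key(crit$termCodes[[1]])))
  if (!is.null(crit$timeRestriction) && is.null(entry$timeRestrictionParameter))
    fq_abort("fq_translation_error",
             sprintf("criterion %s has a timeRestriction but its mapping lacks a timeRestrictionParameter",
                     term_code_key(crit$termCodes[[1]])))

  tail_params <- c(
    if (!is.null(crit$valueFilter))
      value_filter_parameters(crit$valueFilter, entry$valueSearchParameter),
    if (!is.null(crit$timeRestriction))
      time_restriction_parameters(crit$timeRestriction,
                                  entry$timeRestrictionParameter))

  if (is.null(entry$termCodeSearchParameter)) {
    # concept addressed purely through its value/date parameters
    # (e.g. Patient?gender=female)
    if (length(tail_params) == 0L)
      fq_abort("fq_translation_error",
               sprintf("criterion %s has neither a termCodeSearchParameter nor filters",
                       term_code_key(crit$termCodes[[1]])))
    return(list(atomic_query(entry$fhirResourceType, tail_params,
                             sourceCriterion = crit)))
  }

  expanded <- unlist(lapply(crit$termCodes, function(tc) expand_code(tree, tc)),
                     recursive = FALSE)
  keys <- vapply(expanded, term_code_key, character(1))
  expanded <- expanded[!duplicated(keys)]
  tokens <- vapply(expanded, render_token, character(1))
  lapply(chunk_vector(tokens, chunk_size), function(chunk) {
    atomic_query(entry$fhirResourceType,
                 c(list(c(entry$termCodeSearchParameter,
                          paste(chunk, collapse = ","))),
                   tail_params),
                 sourceCriterion = crit)
  })
}

#' Build the FHIR Search execution plan of a Structured Query
#'
#' The plan mirrors the query's structure exactly: one bundle of atomic
#' queries per criterion (a bundle's results are unioned), grouped as in
#' the query's CNF inclusion / DNF exclusion lists. The first untranslatable
#' criterion aborts the whole plan; criteria are never silently dropped.
#'
#' @inheritParams criterion_to_queries
#' @param q an [structured_query()].
#' @return An object of class `fq_execution_plan` with elements `inclusion`
#'   and `exclusion` (lists of groups of bundles) and `chunk_size`.
#' @export
build_plan <- function(q, tree, mapping, chunk_size = 200) {
  stopifnot(inherits(q, "fq_structured_query"))
  translate_groups <- function(groups) {
    lapply(groups, function(g)
      lapply(g, criterion_to_queries, tree = tree, mapping = mapping,
             chunk_size = chunk_size))
  }
  structure(list(inclusion = translate_groups(q$inclusionCriteria),
                 exclusion = translate_groups(q$exclusionCriteria),
                 chunk_size = chunk_size),
            class = "fq_execution_plan")
}

#' @export
print.fq_execution_plan <- function(x, ...) {
  n_atomic <- function(groups) sum(vapply(groups, function(g)
    sum(lengths(g)), numeric(1)))
  cat(sprintf("<execution plan> %d inclusion group(s), %d exclusion group(s), %d atomic quer%s\n",
              length(x$inclusion), length(x$exclusion),
              n_atomic(x$inclusion) + n_atomic(x$exclusion),
              if (n_atomic(x$inclusion) + n_atomic(x$exclusion) == 1) "y" else "ies"))
  invisible(x)
}

#' All rendered URLs of a plan, in execution order
#' @param plan an `fq_execution_plan`.
#' @return Character vector of relative search URLs.
#' @export
plan_urls <- function(plan) {
  stopifnot(inherits(plan, "fq_execution_plan"))
  unlist(lapply(c(plan$inclusion, plan$exclusion), function(g)
    lapply(g, function(bundle) vapply(bundle, render_query_url, character(1)))),
    use.names = FALSE) %||% character(0)
}
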
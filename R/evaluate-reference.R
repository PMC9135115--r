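#' Brute-force reference evaluation of a Structured Query
#'
#' Evaluates the CNF/DNF semantic contract directly, patient by patient,
#' from precomputed truth assignments: a patient matches iff every inclusion
#' group contains at least one satisfied criterion, and no exclusion group
#' has all of its criteria satisfied. This is the oracle against which the
#' set-algebra executor is verified; it never touches a resource store.
#'
#' @param q an [structured_query()].
#' @param patient_facts named list: one element per patient (names are
#'   patient IDs), each a character vector of [criterion_key()] strings for
#'   the criteria that patient satisfies.
#' @return Character vector of matching patient IDs (in input order).
#' @export
evaluate_reference <- function(q, patient_facts) {
  stopifnot(inherits(q, "fq_structured_query"))
  if (length(patient_facts) && is.null(names(patient_facts)))
    fq_abort("fq_validation_error", "patient_facts must be a named list")
  incl_keys <- lapply(q$inclusionCriteria, function(g)
    vapply(g, criterion_key, character(1)))
  excl_keys <- lapply(q$exclusionCriteria, function(g)
    vapply(g, criterion_key, character(1)))
  matches <- vapply(patient_facts, function(sat) {
    included <- all(vapply(incl_keys, function(g) any(g %in% sat), logical(1)))
    excluded <- length(excl_keys) > 0L &&
      any(vapply(excl_keys, function(g) all(g %in% sat), logical(1)))
    included && !excluded
  }, logical(1))
  names(patient_facts)[matches]
}
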
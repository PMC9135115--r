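# Generation of CQL library text for a Structured Query.
#
# Unlike the FHIR Search path, CQL can express a whole feasibility query in
# a single text: one retrieve-based define per criterion and one
# InInitialPopulation define combining them with and/or/not following the
# CNF inclusion and negated DNF exclusion. Only text generation lives here;
# execution is the job of a CQL-capable FHIR server.

cql_quote <- function(s) paste0("'", gsub("'", "\\\\'", s), "'")

# clinical date property per resource type, used for time restrictions
cql_date_property <- function(resourceType) {
  switch(resourceType,
         Condition = "recordedDate",
         Procedure = "performed",
         Observation = "effective",
         Patient = "birthDate",
         fq_abort("fq_translation_error",
                  sprintf("no clinical date property for resource type %s",
                          resourceType)))
}

cql_criterion_define <- function(crit, index, tree, mapping, cs_alias) {
  entry0 <- lookup_mapping(mapping, crit$termCodes[[1]])
  rtype <- entry0$fhirResourceType
  display <- crit$termCodes[[1]]$display %||% term_code_key(crit$termCodes[[1]])
  name <- sprintf("Criterion_%d", index)

  clauses <- character(0)
  if (!is.null(crit$valueFilter)) {
    vf <- crit$valueFilter
    if (vf$kind == "concept") {
      if (rtype == "Patient") {
        # patient-level coded attribute, e.g. administrative gender
        vals <- vapply(vf$selectedConcepts, function(tc)
          sprintf("Patient.%s = %s", entry0$valueSearchParameter %||% "gender",
                  cql_quote(tc$code)), character(1))
        body <- paste0("(", paste(vals, collapse = " or "), ")")
        return(list(name = name,
                    text = sprintf("define %s: // %s\n  %s", name, display, body)))
      }
      vals <- vapply(vf$selectedConcepts, function(tc)
        sprintf("(R.value as CodeableConcept) ~ Code %s from %s",
                cql_quote(tc$code), cs_alias[[tc$system]]), character(1))
      clauses <- c(clauses, paste0("(", paste(vals, collapse = " or "), ")"))
    } else if (vf$kind == "quantity-comparator") {
      op <- switch(vf$comparator, gt = ">", ge = ">=", lt = "<", le = "<=", eq = "=")
      clauses <- c(clauses, sprintf("(R.value as Quantity) %s %s %s", op,
                                    format_decimal(vf$value), cql_quote(vf$unit)))
    } else {
      clauses <- c(clauses,
                   sprintf("(R.value as Quantity) >= %s %s",
                           format_decimal(vf$minValue), cql_quote(vf$unit)),
                   sprintf("(R.value as Quantity) <= %s %s",
                           format_decimal(vf$maxValue), cql_quote(vf$unit)))
    }
  }
  if (!is.null(crit$timeRestriction)) {
    tr <- crit$timeRestriction
    prop <- sprintf("(R.%s as dateTime)", cql_date_property(rtype))
    if (!is.null(tr$afterDate))
      clauses <- c(clauses, sprintf("%s >= @%s", prop, tr$afterDate))
    if (!is.null(tr$beforeDate))
      clauses <- c(clauses, sprintf("%s <= @%s", prop, tr$beforeDate))
  }

  expanded <- unlist(lapply(crit$termCodes, function(tc) expand_code(tree, tc)),
                     recursive = FALSE)
  keys <- vapply(expanded, term_code_key, character(1))
  expanded <- expanded[!duplicated(keys)]
  retrieves <- vapply(expanded, function(tc)
    sprintf("[%s: Code %s from %s]", rtype, cql_quote(tc$code),
            cs_alias[[tc$system]]), character(1))
  retrieve <- if (length(retrieves) == 1L) retrieves else
    paste0("(", paste(retrieves, collapse = " union "), ")")
  body <- if (length(clauses))
    sprintf("exists (%s R where %s)", retrieve, paste(clauses, collapse = " and "))
  else
    sprintf("exists %s", retrieve)
  list(name = name, text = sprintf("define %s: // %s\n  %s", name, display, body))
}

#' Translate a Structured Query into CQL library text
#'
#' Emits a complete, deterministic CQL library: `library` header,
#' `using FHIR`, one `codesystem` declaration per distinct code system used
#' by any criterion (aliases `cs0`, `cs1`, ... in first-use order),
#' `context Patient`, one named define per criterion (`Criterion_<k>` in
#' document order, inclusion before exclusion), and a final
#' `define InInitialPopulation` whose boolean expression realizes the CNF
#' inclusion and negated DNF exclusion contract. Identical queries yield
#' byte-identical text.
#'
#' @param q an [structured_query()].
#' @param tree an `fq_term_tree` for subtype expansion.
#' @param mapping an `fq_mapping_table`.
#' @param library_name identifier used in the `library` header.
#' @return A single string of CQL text.
#' @export
translate_to_cql <- function(q, tree, mapping, library_name = "FeasibilityQuery") {
  stopifnot(inherits(q, "fq_structured_query"))
  crits <- query_criteria(q)
  for (cr in crits) for (tc in cr$termCodes) lookup_mapping(mapping, tc)

  # code systems in first-use order, covering tree-expanded codes too
  systems <- character(0)
  for (cr in crits) {
    expanded <- unlist(lapply(cr$termCodes, function(tc) expand_code(tree, tc)),
                       recursive = FALSE)
    for (tc in expanded) systems <- union(systems, tc$system)
  }
  cs_alias <- setNames(sprintf("cs%d", seq_along(systems) - 1L), systems)

  defines <- lapply(seq_along(crits), function(i)
    cql_criterion_define(crits[[i]], i, tree, mapping, cs_alias))
  names_by_index <- vapply(defines, `[[`, character(1), "name")

  n_incl <- sum(lengths(q$inclusionCriteria))
  idx <- 0L
  incl_expr <- vapply(q$inclusionCriteria, function(g) {
    refs <- names_by_index[idx + seq_along(g)]
    idx <<- idx + length(g)
    if (length(refs) == 1L) refs else
      paste0("(", paste(refs, collapse = " or "), ")")
  }, character(1))
  incl <- if (length(incl_expr) == 1L) incl_expr else
    paste(incl_expr, collapse = " and ")

  excl <- NULL
  if (length(q$exclusionCriteria)) {
    idx <- n_incl
    excl_expr <- vapply(q$exclusionCriteria, function(g) {
      refs <- names_by_index[idx + seq_along(g)]
      idx <<- idx + length(g)
      if (length(refs) == 1L) refs else
        paste0("(", paste(refs, collapse = " and "), ")")
    }, character(1))
    excl <- if (length(excl_expr) == 1L) excl_expr else
      paste0("(", paste(excl_expr, collapse = " or "), ")")
  }

  population <- if (is.null(excl)) incl else
    sprintf("(%s) and not (%s)", incl, excl)

  paste0(
    sprintf("library %s version '1.0.0'\n", library_name),
    "using FHIR version '4.0.0'\n\n",
    paste(vapply(systems, function(s)
      sprintf("codesystem %s: %s", cs_alias[[s]], cql_quote(s)), character(1)),
      collapse = "\n"),
    "\n\ncontext Patient\n\n",
    paste(vapply(defines, `[[`, character(1), "text"), collapse = "\n\n"),
    "\n\ndefine InInitialPopulation:\n  ", population, "\n")
}
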
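# Set-algebra execution of FHIR Search plans (the feasibility executor).
#
# Each atomic search yields a set of patient IDs; the sets are recombined
# following the CNF/DNF contract: union within a criterion bundle (chunks)
# and within an inclusion group, intersection across inclusion groups;
# intersection within an exclusion group, union across exclusion groups;
# final cohort = inclusion minus exclusion. All atomic queries are executed
# (no short-circuiting), so the resources-processed accounting is
# deterministic and reflects the worst case.

#' Execute an execution plan against a resource store
#'
#' @param plan an [build_plan()] result.
#' @param store an `fq_resource_store`.
#' @return An object of class `fq_execution_result` with fields
#'   `patientCount` (exact, pre-obfuscation), `patientIds` (character set),
#'   and `resourcesProcessed` (total number of resources returned across all
#'   atomic queries).
#' @export
execute_plan <- function(plan, store) {
  stopifnot(inherits(plan, "fq_execution_plan"),
            inherits(store, "fq_resource_store"))
  if (length(plan$inclusion) == 0L)
    fq_abort("fq_validation_error", "execution plan has no inclusion groups")
  processed <- 0L

  run_bundle <- function(bundle) {
    ids <- character(0)
    for (q in bundle) {
      hits <- store_search(store, q)
      processed <<- processed + nrow(hits)
      ids <- union(ids, patient_ids(hits))
    }
    ids
  }
  run_group <- function(group, combine) {
    sets <- lapply(group, run_bundle)
    Reduce(combine, sets)
  }

  inclusion_sets <- lapply(plan$inclusion, run_group, combine = union)
  included <- Reduce(intersect, inclusion_sets)

  excluded <- character(0)
  for (group in plan$exclusion)
    excluded <- union(excluded, run_group(group, combine = intersect))

  final <- setdiff(included, excluded)
  structure(list(patientCount = length(final),
                 patientIds = final,
                 resourcesProcessed = processed),
            class = "fq_execution_result")
}

#' @export
print.fq_execution_result <- function(x, ...) {
  cat(sprintf("<execution result> %s patient(s), %s resource(s) processed\n",
              format(x$patientCount, big.mark = ","),
              format(x$resourcesProcessed, big.mark = ",")))
  invisible(x)
}

#' Count the patients matching a Structured Query
#'
#' Convenience composition: [build_plan()] then [execute_plan()]. Returns
#' the exact (pre-obfuscation) count; apply [obfuscate()] before a count
#' leaves a site.
#'
#' @param q an [structured_query()].
#' @param store an `fq_resource_store`.
#' @param tree an `fq_term_tree`.
#' @param mapping an `fq_mapping_table`.
#' @param chunk_size codes per atomic query (default 200).
#' @return An `fq_execution_result`.
#' @export
count_query <- function(q, store, tree, mapping, chunk_size = 200) {
  execute_plan(build_plan(q, tree, mapping, chunk_size = chunk_size), store)
}
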
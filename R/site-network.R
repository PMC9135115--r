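# Simulation of the central broker and the decentral sites.
#
# The broker never pushes into a hospital: it parks a query envelope, and
# each registered site pulls it, executes the query locally through its
# configured path, obfuscates the count, and returns only the obfuscated
# result. The simulation is in-process; the broker/site boundary is an
# interface contract (envelope in, SiteResult out) that a real transport
# could replace without touching the query semantics.

#' Build a query envelope carrying both query representations
#'
#' The envelope is what crosses the network: the Structured Query JSON and
#' the CQL library text, generated centrally from the same query so each
#' site can pick the representation its stack executes.
#'
#' @param q an [structured_query()].
#' @param tree an `fq_term_tree`.
#' @param mapping an `fq_mapping_table`.
#' @param queryId opaque identifier; defaults to a hash-free deterministic
#'   id derived from the serialized query length and version.
#' @param issuedAt ISO-8601 timestamp string.
#' @return An object of class `fq_query_envelope` with fields `queryId`,
#'   `structuredQuery` (JSON text), `cqlText`, `issuedAt`.
#' @export
query_envelope <- function(q, tree, mapping, queryId = NULL,
                           issuedAt = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC")) {
  sq_json <- serialize_structured_query(q)
  cql <- translate_to_cql(q, tree, mapping)
  if (is.null(queryId))
    queryId <- sprintf("query-%08x", sum(utf8ToInt(sq_json) *
                                           (seq_len(nchar(sq_json)) %% 997)) %% .Machine$integer.max)
  structure(list(queryId = queryId, structuredQuery = sq_json, cqlText = cql,
                 issuedAt = issuedAt),
            class = "fq_query_envelope")
}

#' Register a decentral site
#'
#' @param siteId unique site identifier.
#' @param store the site's local `fq_resource_store`.
#' @param tree,mapping the site's terminology tree and mapping table (the
#'   translation into FHIR Search happens inside the site).
#' @param executionPath `"fhir-search"`. The value `"cql"` is part of the
#'   envelope contract but no CQL engine ships here, so configuring it is
#'   rejected at site-construction time with a clear message.
#' @param chunk_size codes per atomic query for this site's translator.
#' @return An object of class `fq_site`.
#' @export
feas_site <- function(siteId, store, tree, mapping,
                      executionPath = "fhir-search", chunk_size = 200) {
  if (!is_nonempty_string(siteId))
    fq_abort("fq_validation_error", "siteId must be a non-empty string")
  if (identical(executionPath, "cql"))
    fq_abort("fq_config_error",
             paste0("site '", siteId, "': execution path 'cql' is reserved; ",
                    "no CQL engine is available — configure 'fhir-search'"))
  if (!identical(executionPath, "fhir-search"))
    fq_abort("fq_config_error",
             sprintf("site '%s': unknown execution path '%s'", siteId,
                     executionPath))
  stopifnot(inherits(store, "fq_resource_store"))
  structure(list(siteId = siteId, store = store, tree = tree,
                 mapping = mapping, executionPath = executionPath,
                 chunk_size = chunk_size),
            class = "fq_site")
}

site_pull_and_execute <- function(site, envelope) {
  q <- parse_structured_query(envelope$structuredQuery)
  res <- count_query(q, site$store, site$tree, site$mapping,
                     chunk_size = site$chunk_size)
  obfuscate(res$patientCount)
}

#' Broadcast a query envelope to all registered sites
#'
#' Each site pulls the envelope, executes it through its configured path,
#' and reports an obfuscated count. Failures are isolated per site: an
#' error at one site yields a `status = "error"` result there and leaves
#' every other site's result untouched. A site whose execution exceeds
#' `timeout` seconds reports `status = "timeout"` (and no count). Exact
#' counts never appear in a site result.
#'
#' @param envelope an [query_envelope()].
#' @param sites non-empty list of [feas_site()] objects with unique ids.
#' @param timeout per-site wall-clock budget in seconds.
#' @return List of site results ordered by `siteId`, each a list with
#'   `siteId`, `status` (`"ok"`, `"timeout"`, `"error"`), and
#'   `obfuscatedCount` (present iff ok).
#' @export
broadcast <- function(envelope, sites, timeout = 30) {
  stopifnot(inherits(envelope, "fq_query_envelope"))
  if (length(sites) == 0L)
    fq_abort("fq_config_error", "no sites registered")
  ids <- vapply(sites, `[[`, character(1), "siteId")
  if (anyDuplicated(ids))
    fq_abort("fq_config_error",
             sprintf("duplicate siteId '%s'", ids[duplicated(ids)][1]))
  sites <- sites[order(ids)]
  lapply(sites, function(site) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(
      list(status = "ok", count = site_pull_and_execute(site, envelope)),
      error = function(e) list(status = "error",
                               message = conditionMessage(e)))
    elapsed <- proc.time()[["elapsed"]] - t0
    if (elapsed > timeout) out <- list(status = "timeout")
    res <- list(siteId = site$siteId, status = out$status)
    if (out$status == "ok") res$obfuscatedCount <- out$count
    if (out$status == "error") res$message <- out$message
    res
  })
}

#' Summarize a broadcast into a central report
#'
#' Lists the per-site obfuscated counts, their total, and how many sites
#' timed out or errored. Whenever any site is not ok, the total is flagged
#' `partial = TRUE`: it is a lower bound on the network-wide count.
#'
#' @param results the list returned by [broadcast()].
#' @return A list with `sites` (siteId, status, obfuscatedCount), `total`,
#'   `okSites`, `timeoutSites`, `errorSites`, `partial`; class `fq_report`.
#' @export
summarize_results <- function(results) {
  statuses <- vapply(results, `[[`, character(1), "status")
  counts <- vapply(results, function(r)
    if (identical(r$status, "ok")) as.integer(r$obfuscatedCount) else NA_integer_,
    integer(1))
  structure(list(
    sites = lapply(results, function(r)
      list(siteId = r$siteId, status = r$status,
           obfuscatedCount = if (identical(r$status, "ok"))
             as.integer(r$obfuscatedCount))),
    total = sum(counts, na.rm = TRUE),
    okSites = sum(statuses == "ok"),
    timeoutSites = sum(statuses == "timeout"),
    errorSites = sum(statuses == "error"),
    partial = any(statuses != "ok")),
    class = "fq_report")
}

#' @export
print.fq_report <- function(x, ...) {
  cat("<feasibility report>\n")
  for (s in x$sites)
    cat(sprintf("  %-12s %-8s %s\n", s$siteId, s$status,
                if (!is.null(s$obfuscatedCount)) s$obfuscatedCount else ""))
  cat(sprintf("  total: %d%s\n", x$total,
              if (x$partial) " (partial — lower bound)" else ""))
  invisible(x)
}

#' Serialize a report as JSON
#' @param report an `fq_report`.
#' @return JSON text.
#' @export
report_to_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}
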
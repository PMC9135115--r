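# Terminology tree and FHIR mapping table.
#
# The tree is the concept hierarchy researchers navigate in a query UI;
# selecting a parent concept implies all its subtypes, so translation
# expands a code to itself plus all descendants. The mapping table carries
# per-concept translation metadata: which FHIR resource type answers the
# concept and which search parameters address its code, value and date.

#' Build a terminology tree
#'
#' A forest of concept nodes, each `list(termCode = , children = list(...))`.
#' `(system, code)` pairs must be unique across the whole forest and the
#' structure must be acyclic (guaranteed by the nested-list representation;
#' duplicate keys are rejected).
#'
#' @param roots list of nodes; each node has a `termCode` ([term_code()])
#'   and a possibly empty list `children` of nodes.
#' @return An object of class `fq_term_tree`.
#' @export
term_tree <- function(roots) {
  seen <- new.env(parent = emptyenv())
  walk <- function(node, path) {
    if (!is.list(node) || !inherits(node$termCode, "fq_term_code"))
      fq_abort("fq_validation_error",
               sprintf("tree node at %s lacks a valid termCode", path))
    key <- term_code_key(node$termCode)
    if (!is.null(seen[[key]]))
      fq_abort("fq_validation_error",
               sprintf("duplicate term code %s in terminology tree", key))
    assign(key, TRUE, envir = seen)
    kids <- node$children %||% list()
    node$children <- lapply(seq_along(kids), function(i)
      walk(kids[[i]], sprintf("%s.children[%d]", path, i)))
    node
  }
  roots <- lapply(seq_along(roots), function(i)
    walk(roots[[i]], sprintf("$[%d]", i)))
  structure(list(roots = roots), class = "fq_term_tree")
}

tree_node_from_list <- function(x, path) {
  check_fields(x, c("termCode", "children"), path)
  list(termCode = term_code_from_list(x$termCode, paste0(path, ".termCode")),
       children = lapply(seq_along(x$children %||% list()), function(i)
         tree_node_from_list(x$children[[i]], sprintf("%s.children[%d]", path, i))))
}

#' Read a terminology-tree JSON file
#'
#' The file holds a JSON array of root nodes, each
#' `{"termCode": {...}, "children": [...]}`.
#'
#' @param path file path.
#' @return An `fq_term_tree`.
#' @export
read_term_tree <- function(path) {
  doc <- jsonlite::parse_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
  term_tree(lapply(seq_along(doc), function(i)
    tree_node_from_list(doc[[i]], sprintf("$[%d]", i))))
}

tree_node_to_list <- function(node) {
  list(termCode = term_code_to_list(node$termCode),
       children = lapply(node$children, tree_node_to_list))
}

#' Serialize a terminology tree back to JSON text (lossless)
#' @param tree an `fq_term_tree`.
#' @return JSON text.
#' @export
serialize_term_tree <- function(tree) {
  as.character(jsonlite::toJSON(lapply(tree$roots, tree_node_to_list),
                                auto_unbox = TRUE, digits = NA))
}

#' Expand a code to itself plus all hierarchical descendants
#'
#' Selecting a parent concept (e.g. ICD-10 E11, Diabetes mellitus Type 2)
#' implies all its subtypes (E11.0, E11.1, ...). The expansion returns the
#' code itself first, followed by all descendants in depth-first pre-order —
#' the parent is always included because data may be coded at the parent
#' level. A code absent from the tree expands to itself alone (absence is
#' not an error: the tree only adds subtypes, it does not gate codes).
#'
#' @param tree an `fq_term_tree`.
#' @param code an [term_code()].
#' @return List of `fq_term_code`, the code followed by its descendants.
#' @export
expand_code <- function(tree, code) {
  stopifnot(inherits(tree, "fq_term_tree"), inherits(code, "fq_term_code"))
  key <- term_code_key(code)
  find <- function(node) {
    if (term_code_key(node$termCode) == key) return(node)
    for (child in node$children) {
      hit <- find(child)
      if (!is.null(hit)) return(hit)
    }
    NULL
  }
  hit <- NULL
  for (root in tree$roots) {
    hit <- find(root)
    if (!is.null(hit)) break
  }
  if (is.null(hit)) return(list(code))
  collect <- function(node) {
    c(list(node$termCode), unlist(lapply(node$children, collect),
                                  recursive = FALSE))
  }
  collect(hit)
}

#' Build a mapping table
#'
#' @param entries list of mapping entries, each created by [mapping_entry()].
#' @return An object of class `fq_mapping_table` (keyed for O(1) lookup).
#' @export
mapping_table <- function(entries) {
  if (!all(vapply(entries, inherits, logical(1), "fq_mapping_entry")))
    fq_abort("fq_validation_error", "entries must be created with mapping_entry()")
  keys <- vapply(entries, function(e) term_code_key(e$key), character(1))
  if (anyDuplicated(keys))
    fq_abort("fq_validation_error",
             sprintf("duplicate mapping key %s", keys[duplicated(keys)][1]))
  structure(list(entries = setNames(entries, keys)), class = "fq_mapping_table")
}

#' Create one mapping entry
#'
#' Translation metadata for one concept: the FHIR resource type it lives on
#' and the search parameters addressing its code, value and clinical date.
#' Patient-level concepts (e.g. administrative gender) typically have no
#' `termCodeSearchParameter`; their selection is expressed entirely through
#' the value parameter.
#'
#' @param key the concept's [term_code()].
#' @param fhirResourceType e.g. `"Condition"`, `"Observation"`, `"Patient"`.
#' @param termCodeSearchParameter token parameter carrying the code list,
#'   e.g. `"code"`; `NULL` for concepts addressed by value only.
#' @param valueSearchParameter parameter for value filters, e.g.
#'   `"value-quantity"` or `"gender"`.
#' @param timeRestrictionParameter date parameter, e.g. `"recorded-date"`.
#' @return An object of class `fq_mapping_entry`.
#' @export
mapping_entry <- function(key, fhirResourceType, termCodeSearchParameter = NULL,
                          valueSearchParameter = NULL,
                          timeRestrictionParameter = NULL) {
  stopifnot(inherits(key, "fq_term_code"))
  if (!is_nonempty_string(fhirResourceType))
    fq_abort("fq_validation_error", "fhirResourceType must be non-empty")
  for (p in list(termCodeSearchParameter, valueSearchParameter,
                 timeRestrictionParameter))
    if (!is.null(p) && !is_nonempty_string(p))
      fq_abort("fq_validation_error", "search parameters must be non-empty strings")
  structure(list(key = key, fhirResourceType = fhirResourceType,
                 termCodeSearchParameter = termCodeSearchParameter,
                 valueSearchParameter = valueSearchParameter,
                 timeRestrictionParameter = timeRestrictionParameter),
            class = "fq_mapping_entry")
}

#' Read a FHIR mapping JSON file
#'
#' The file holds a JSON array of entries
#' `{"key": {"system": ..., "code": ...}, "fhirResourceType": ...,
#' "termCodeSearchParameter": ..., "valueSearchParameter": ...,
#' "timeRestrictionParameter": ...}` (parameter fields optional).
#'
#' @param path file path.
#' @return An `fq_mapping_table`.
#' @export
read_mapping_table <- function(path) {
  doc <- jsonlite::parse_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
  mapping_table(lapply(seq_along(doc), function(i) {
    x <- doc[[i]]
    check_fields(x, c("key", "fhirResourceType", "termCodeSearchParameter",
                      "valueSearchParameter", "timeRestrictionParameter"),
                 sprintf("$[%d]", i))
    mapping_entry(term_code_from_list(x$key, sprintf("$[%d].key", i)),
                  x$fhirResourceType %||% "",
                  termCodeSearchParameter = x$termCodeSearchParameter,
                  valueSearchParameter = x$valueSearchParameter,
                  timeRestrictionParameter = x$timeRestrictionParameter)
  }))
}

#' Serialize a mapping table back to JSON text (lossless)
#' @param mapping an `fq_mapping_table`.
#' @return JSON text.
#' @export
serialize_mapping_table <- function(mapping) {
  out <- lapply(unname(mapping$entries), function(e) {
    x <- list(key = term_code_to_list(e$key),
              fhirResourceType = e$fhirResourceType)
    if (!is.null(e$termCodeSearchParameter))
      x$termCodeSearchParameter <- e$termCodeSearchParameter
    if (!is.null(e$valueSearchParameter))
      x$valueSearchParameter <- e$valueSearchParameter
    if (!is.null(e$timeRestrictionParameter))
      x$timeRestrictionParameter <- e$timeRestrictionParameter
    x
  })
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
}

#' Look up the mapping entry for a code
#'
#' Lookup is by `(system, code)`. A missing entry is a hard error
#' (`fq_mapping_not_found`) naming the code: translation must fail loudly
#' rather than silently dropping a criterion, which would inflate cohorts.
#'
#' @param mapping an `fq_mapping_table`.
#' @param code an [term_code()].
#' @return The `fq_mapping_entry`.
#' @export
lookup_mapping <- function(mapping, code) {
  stopifnot(inherits(mapping, "fq_mapping_table"), inherits(code, "fq_term_code"))
  entry <- mapping$entries[[term_code_key(code)]]
  if (is.null(entry))
    fq_abort("fq_mapping_not_found",
             sprintf("no mapping entry for code %s", term_code_key(code)),
             code = code)
  entry
}
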
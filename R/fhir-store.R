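# In-memory FHIR R4 resource store and FHIR Search evaluator.
#
# Stands in for a hospital FHIR server for the four resource types of the
# benchmark design (Patient, Condition, Procedure, Observation). Resources
# live in one column-oriented data frame per type; clinical resources may
# occupy several rows when they carry several codings (one row per coding),
# so searches match rows and then deduplicate by resource id.

empty_patients <- function() {
  data.frame(id = character(0), gender = character(0), birthDate = character(0),
             stringsAsFactors = FALSE)
}

empty_clinical <- function(type) {
  df <- data.frame(id = character(0), system = character(0), code = character(0),
                   subject = character(0), date = character(0),
                   stringsAsFactors = FALSE)
  if (type == "Observation") {
    df$value <- numeric(0); df$unit <- character(0); df$valueSystem <- character(0)
  }
  df
}

STORE_TYPES <- c("Patient", "Condition", "Procedure", "Observation")

# JSON date field per clinical type (internally the column is always `date`)
CLINICAL_DATE_FIELD <- c(Condition = "recordedDate",
                         Procedure = "performedDateTime",
                         Observation = "effectiveDateTime")

#' Construct a resource store from column-oriented tables
#'
#' Mostly used internally (the synthetic-data generator builds stores this
#' way) and by [read_store()]. Each clinical table has one row per coding
#' with columns `id`, `system`, `code`, `subject` (patient id) and `date`;
#' observations additionally `value`, `unit`, `valueSystem`.
#'
#' @param patients data frame with columns `id`, `gender`, `birthDate`.
#' @param conditions,procedures,observations clinical tables (see above).
#' @param lenient if `FALSE` (default), a subject referencing no stored
#'   patient is an error.
#' @return An object of class `fq_resource_store`.
#' @export
resource_store <- function(patients = empty_patients(),
                           conditions = empty_clinical("Condition"),
                           procedures = empty_clinical("Procedure"),
                           observations = empty_clinical("Observation"),
                           lenient = FALSE) {
  if (anyDuplicated(patients$id))
    fq_abort("fq_validation_error", "duplicate Patient ids")
  store <- structure(list(Patient = patients, Condition = conditions,
                          Procedure = procedures, Observation = observations),
                     class = "fq_resource_store")
  if (!lenient) {
    for (type in c("Condition", "Procedure", "Observation")) {
      df <- store[[type]]
      bad <- is.na(df$subject) | !nzchar(df$subject) |
        !(df$subject %in% patients$id)
      if (any(bad))
        fq_abort("fq_validation_error",
                 sprintf("%s %s references no stored Patient (subject '%s')",
                         type, df$id[bad][1], df$subject[bad][1]))
    }
  }
  store
}

#' Resource counts per type
#' @param store an `fq_resource_store`.
#' @return Named integer vector over Patient, Condition, Procedure,
#'   Observation plus `Total` (resources, not coding rows).
#' @export
store_census <- function(store) {
  stopifnot(inherits(store, "fq_resource_store"))
  n <- vapply(STORE_TYPES, function(type) {
    df <- store[[type]]
    if (anyDuplicated(df$id)) length(unique(df$id)) else nrow(df)
  }, numeric(1))
  c(n, Total = sum(n))
}

#' @export
print.fq_resource_store <- function(x, ...) {
  census <- store_census(x)
  cat("<FHIR resource store>\n")
  for (nm in names(census))
    cat(sprintf("  %-12s %s\n", nm, format(census[[nm]], big.mark = ",")))
  invisible(x)
}

# ---- search ---------------------------------------------------------------

match_token_list <- function(systems, codes, value) {
  tokens <- strsplit(value, ",", fixed = TRUE)[[1]]
  mask <- rep(FALSE, length(codes))
  for (tok in tokens) {
    bar <- regexpr("|", tok, fixed = TRUE)
    if (bar == -1L) {
      mask <- mask | (codes == percent_decode(tok))
    } else {
      sys <- percent_decode(substr(tok, 1L, bar - 1L))
      cod <- percent_decode(substr(tok, bar + 1L, nchar(tok)))
      mask <- mask | (systems == sys & codes == cod)
    }
  }
  mask
}

match_date <- function(dates, value) {
  prefix <- substr(value, 1L, 2L)
  if (!prefix %in% c("ge", "le"))
    fq_abort("fq_unsupported_search",
             sprintf("unsupported date prefix in '%s' (only ge/le)", value))
  bound <- substr(value, 3L, nchar(value))
  if (!is_iso_date(bound))
    fq_abort("fq_unsupported_search", sprintf("malformed date value '%s'", value))
  d <- as.Date(dates); b <- as.Date(bound)
  ok <- if (prefix == "ge") d >= b else d <= b
  ok & !is.na(d)
}

match_quantity <- function(values, units, value_systems, spec) {
  prefix <- substr(spec, 1L, 2L)
  if (!prefix %in% c("gt", "ge", "lt", "le", "eq"))
    fq_abort("fq_unsupported_search",
             sprintf("unsupported quantity prefix in '%s'", spec))
  rest <- substr(spec, 3L, nchar(spec))
  parts <- strsplit(rest, "|", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(parts[[1]]))
  if (is.na(num))
    fq_abort("fq_unsupported_search", sprintf("malformed quantity value '%s'", spec))
  mask <- switch(prefix,
                 gt = values > num, ge = values >= num,
                 lt = values < num, le = values <= num,
                 eq = values == num)
  if (length(parts) >= 3L) {
    mask <- mask & (value_systems == percent_decode(parts[[2]])) &
      (units == percent_decode(parts[[3]]))
  } else if (length(parts) == 2L) {
    fq_abort("fq_unsupported_search",
             sprintf("quantity token '%s' must be value or value|system|unit", spec))
  }
  mask & !is.na(values)
}

# supported search parameters per resource type -> matcher dispatch
search_param_matcher <- function(resourceType, name) {
  key <- paste(resourceType, name)
  switch(key,
    "Patient gender" = function(df, value) {
      # gender is a token parameter; accept bare code or system|code
      match_token_list(rep(ADMIN_GENDER_SYSTEM, nrow(df)), df$gender, value)
    },
    "Patient birthdate" = function(df, value) match_date(df$birthDate, value),
    "Condition code" = ,
    "Procedure code" = ,
    "Observation code" = function(df, value)
      match_token_list(df$system, df$code, value),
    "Condition recorded-date" = ,
    "Procedure date" = ,
    "Observation date" = function(df, value) match_date(df$date, value),
    "Observation value-quantity" = function(df, value)
      match_quantity(df$value, df$unit, df$valueSystem, value),
    fq_abort("fq_unsupported_search",
             sprintf("unsupported search parameter '%s' on %s", name, resourceType))
  )
}

#' Evaluate one atomic FHIR Search query against the store
#'
#' Implements the FHIR Search subset the translator emits: token parameters
#' on `code`/`gender` (comma = OR within the list, `system|code` requires
#' both to match, a bare code matches any system), quantity prefixes
#' gt/ge/lt/le/eq on `value-quantity` (unit and system must match when given
#' in the token; `eq` is exact decimal comparison), and date prefixes ge/le
#' at day precision, inclusive. Parameters are ANDed. Any parameter outside
#' the subset raises `fq_unsupported_search` naming it — silently ignoring a
#' parameter would inflate cohorts. The store is never modified.
#'
#' @param store an `fq_resource_store`.
#' @param q an [atomic_query()] or a relative URL string.
#' @return The matching resources as a data frame (one row per resource,
#'   deduplicated by id) with attribute `resourceType`.
#' @export
store_search <- function(store, q) {
  stopifnot(inherits(store, "fq_resource_store"))
  if (is.character(q)) {
    parsed <- parse_query_url(q)
    q <- atomic_query(parsed$resourceType, parsed$parameters)
  }
  stopifnot(inherits(q, "fq_atomic_query"))
  if (!q$resourceType %in% STORE_TYPES)
    fq_abort("fq_unsupported_search",
             sprintf("unsupported resource type '%s'", q$resourceType))
  df <- store[[q$resourceType]]
  mask <- rep(TRUE, nrow(df))
  for (p in q$parameters) {
    matcher <- search_param_matcher(q$resourceType, p[[1]])
    mask <- mask & matcher(df, p[[2]])
  }
  out <- df[mask, , drop = FALSE]
  if (anyDuplicated(out$id)) out <- out[!duplicated(out$id), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "resourceType") <- q$resourceType
  out
}

#' Patient IDs behind a set of search results
#'
#' Patient resources contribute their own ids; clinical resources the
#' patient id of their subject reference. The result is a deduplicated set.
#'
#' @param resources a result of [store_search()].
#' @return Character vector of unique patient IDs.
#' @export
patient_ids <- function(resources) {
  type <- attr(resources, "resourceType")
  if (is.null(type))
    fq_abort("fq_validation_error", "resources must come from store_search()")
  ids <- if (type == "Patient") resources$id else resources$subject
  if (any(is.na(ids) | !nzchar(ids)))
    fq_abort("fq_validation_error",
             sprintf("%s resource without subject reference", type))
  unique(ids)
}

# ---- NDJSON / Bundle I/O --------------------------------------------------

json_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

# Render every resource of the store as one compact JSON string, in a
# deterministic order (Patients, Conditions, Procedures, Observations, each
# in storage order). Vectorized so the full benchmark data sets render in
# seconds. Multi-coding resources are grouped back into one line.
store_resource_lines <- function(store) {
  lines <- character(0)
  p <- store$Patient
  if (nrow(p))
    lines <- c(lines, sprintf(
      '{"resourceType":"Patient","id":"%s","gender":"%s","birthDate":"%s"}',
      json_escape(p$id), json_escape(p$gender), json_escape(p$birthDate)))
  for (type in c("Condition", "Procedure", "Observation")) {
    df <- store[[type]]
    if (!nrow(df)) next
    if (anyDuplicated(df$id)) {
      # group codings of one resource into a single coding array
      keep <- !duplicated(df$id)
      codings <- vapply(split(sprintf('{"system":"%s","code":"%s"}',
                                      json_escape(df$system), json_escape(df$code)),
                              match(df$id, df$id[keep])),
                        paste, character(1), collapse = ",")
      df <- df[keep, , drop = FALSE]
    } else {
      codings <- sprintf('{"system":"%s","code":"%s"}',
                         json_escape(df$system), json_escape(df$code))
    }
    datefield <- CLINICAL_DATE_FIELD[[type]]
    value_part <- if (type == "Observation")
      sprintf(',"valueQuantity":{"value":%s,"unit":"%s","system":"%s","code":"%s"}',
              vapply(df$value, format_decimal, character(1)),
              json_escape(df$unit), json_escape(df$valueSystem),
              json_escape(df$unit))
    else ""
    lines <- c(lines, sprintf(
      '{"resourceType":"%s","id":"%s","code":{"coding":[%s]},"subject":{"reference":"Patient/%s"},"%s":"%s"%s}',
      type, json_escape(df$id), codings, json_escape(df$subject),
      datefield, json_escape(df$date), value_part))
  }
  lines
}

#' Write a store as NDJSON (one resource per line) or a FHIR Bundle
#'
#' Output is deterministic: equal stores produce byte-identical files.
#'
#' @param store an `fq_resource_store`.
#' @param path output file path.
#' @param format `"ndjson"` or `"bundle"` (a Bundle of type `collection`).
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path, format = c("ndjson", "bundle")) {
  format <- match.arg(format)
  lines <- store_resource_lines(store)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "ndjson") {
    writeLines(lines, con, sep = "\n")
  } else {
    writeLines(c('{"resourceType":"Bundle","type":"collection","entry":[',
                 paste0('{"resource":', lines, '}',
                        c(rep(",", max(0L, length(lines) - 1L)), "")),
                 ']}'), con, sep = "\n")
  }
  invisible(path)
}

parse_resource <- function(res, acc, lineno) {
  type <- res$resourceType
  if (is.null(type) || !type %in% STORE_TYPES) {
    warning(sprintf("skipping resource with unknown resourceType '%s' (entry %d)",
                    type %||% "<missing>", lineno), call. = FALSE)
    return(acc)
  }
  id <- res$id %||% fq_abort("fq_parse_error",
                             sprintf("resource without id (entry %d)", lineno))
  if (type == "Patient") {
    acc$Patient[[length(acc$Patient) + 1L]] <-
      data.frame(id = id, gender = res$gender %||% NA_character_,
                 birthDate = res$birthDate %||% NA_character_,
                 stringsAsFactors = FALSE)
    return(acc)
  }
  codings <- res$code$coding %||% list()
  if (length(codings) == 0L)
    codings <- list(list(system = NA_character_, code = NA_character_))
  subject <- sub("^Patient/", "", res$subject$reference %||% "")
  date <- res[[CLINICAL_DATE_FIELD[[type]]]] %||% NA_character_
  rows <- do.call(rbind, lapply(codings, function(cd)
    data.frame(id = id, system = cd$system %||% NA_character_,
               code = cd$code %||% NA_character_, subject = subject,
               date = date, stringsAsFactors = FALSE)))
  if (type == "Observation") {
    vq <- res$valueQuantity
    rows$value <- vq$value %||% NA_real_
    rows$unit <- vq$code %||% vq$unit %||% NA_character_
    rows$valueSystem <- vq$system %||% NA_character_
  }
  acc[[type]][[length(acc[[type]]) + 1L]] <- rows
  acc
}

#' Read FHIR resources from NDJSON or a Bundle into a store
#'
#' Unknown resource types are skipped with a warning; a clinical resource
#' whose subject does not resolve to a loaded Patient is an error unless
#' `lenient = TRUE`.
#'
#' @param path file path.
#' @param format `"ndjson"` (one resource per line) or `"bundle"` (a FHIR
#'   Bundle of type `collection`).
#' @param lenient allow dangling subject references.
#' @return An `fq_resource_store`.
#' @export
read_store <- function(path, format = c("ndjson", "bundle"), lenient = FALSE) {
  format <- match.arg(format)
  acc <- list(Patient = list(), Condition = list(), Procedure = list(),
              Observation = list())
  if (format == "ndjson") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines))
      acc <- parse_resource(jsonlite::parse_json(lines[[i]]), acc, i)
  } else {
    doc <- jsonlite::parse_json(paste(readLines(path, warn = FALSE),
                                      collapse = "\n"))
    if (!identical(doc$resourceType, "Bundle"))
      fq_abort("fq_parse_error", "expected a FHIR Bundle document")
    entries <- doc$entry %||% list()
    for (i in seq_along(entries))
      acc <- parse_resource(entries[[i]]$resource %||% list(), acc, i)
  }
  bind <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty
  resource_store(
    patients = bind(acc$Patient, empty_patients()),
    conditions = bind(acc$Condition, empty_clinical("Condition")),
    procedures = bind(acc$Procedure, empty_clinical("Procedure")),
    observations = bind(acc$Observation, empty_clinical("Observation")),
    lenient = lenient)
}
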
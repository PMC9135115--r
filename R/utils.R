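#' @importFrom stats runif setNames
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Signal a classed feasquery error
#'
#' All domain errors raised by the package carry a subclass of `fq_error`
#' so callers can distinguish, e.g., a missing mapping entry
#' (`fq_mapping_not_found`) from an unsupported search parameter
#' (`fq_unsupported_search`).
#'
#' @param class character subclass, e.g. "fq_validation_error".
#' @param message human-readable message.
#' @param ... further fields stored on the condition object.
#' @keywords internal
fq_abort <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "fq_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_nonempty_string <- function(x) is_string(x) && nzchar(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == trunc(x)
}

#' Split a vector into chunks of at most `size` elements
#' @keywords internal
chunk_vector <- function(x, size) {
  if (length(x) == 0L) return(list())
  split(x, ceiling(seq_along(x) / size))
}

# Percent-encode everything outside the RFC 3986 unreserved set. Applied to
# the atomic pieces of a search value (a system URI, a code, a unit), never
# to the structural separators | , & = ?, so rendered URLs parse back
# unambiguously.
percent_encode <- function(x) {
  vapply(x, function(s) utils::URLencode(s, reserved = TRUE), character(1),
         USE.NAMES = FALSE)
}

percent_decode <- function(x) {
  vapply(x, utils::URLdecode, character(1), USE.NAMES = FALSE)
}

# ISO-8601 calendar date check (day precision only)
is_iso_date <- function(x) {
  is_string(x) && grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &&
    !is.na(as.Date(x, format = "%Y-%m-%d"))
}

# Format a numeric scalar the way it is embedded in search values and CQL
# (plain decimal notation, no scientific format).
format_decimal <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}
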
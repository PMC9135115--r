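#' Obfuscate a patient count before it leaves a site
#'
#' Feasibility results are privacy-protected by aggregation: the exact
#' count is rounded to the nearest multiple of 10 before crossing the site
#' boundary, so the central location never learns a count precise enough to
#' re-identify a patient profile. A result of zero is returned as zero.
#' Ties (counts ending in 5) round up. Consequently counts 1-4 round to 0 —
#' a small-count disclosure trade-off documented with the method.
#'
#' @param n exact non-negative integer patient count.
#' @return An integer multiple of 10, within 5 of `n` (class
#'   `fq_obfuscated_count`).
#' @examples
#' obfuscate(0)     # 0
#' obfuscate(1234)  # 1230
#' obfuscate(1235)  # 1240
#' @export
obfuscate <- function(n) {
  if (!is_count(n))
    fq_abort("fq_validation_error", "count must be a non-negative integer")
  structure(as.integer(10 * (n %/% 10 + (n %% 10 >= 5))),
            class = "fq_obfuscated_count")
}

#' @export
print.fq_obfuscated_count <- function(x, ...) {
  cat(sprintf("<obfuscated count> %d (rounded to nearest 10)\n",
              unclass(x)))
  invisible(x)
}
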
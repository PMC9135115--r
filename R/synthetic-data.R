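# Deterministic generator for the benchmark data sets and query suite.
#
# Each data set consists of planted patient cohorts of exact sizes —
# every cohort member carries exactly one matching Condition, Procedure and
# Observation, plus a patient-level attribute unique to the cohort — so
# every benchmark query has an exactly predictable answer. Two profiles add
# background data (resources no benchmark query targets, spread over many
# codes) emulating the load of a hospital FHIR server.

ICD10_SYSTEM <- "http://fhir.de/CodeSystem/bfarm/icd-10-gm"
OPS_SYSTEM <- "http://fhir.de/CodeSystem/bfarm/ops"
LOINC_SYSTEM <- "http://loinc.org"
SNOMED_SYSTEM <- "http://snomed.info/sct"

GENDER_CONCEPT <- function() term_code(SNOMED_SYSTEM, "263495000", "Gender")
BIRTHDATE_CONCEPT <- function() term_code(SNOMED_SYSTEM, "184099003", "Date of birth")

# fixed per-cohort criterion codes, assigned by cohort position; the cohort
# of size 100,000 always receives the female / C50.1 / 5-787 / 55782-7
# combination
COHORT_CONDITION_CODES <- c("E11.2", "I10.9", "C50.1", "J18.9")
COHORT_PROCEDURE_CODES <- c("5-470.11", "8-100.3", "5-787", "1-632.0")
COHORT_OBSERVATION_CODES <- c("26436-6", "718-7", "55782-7", "2160-0")
COHORT_GENDERS <- c("male", "other", "female", "unknown")

NOMATCH_CONDITION <- "X99.9"
NOMATCH_PROCEDURE <- "9-999.99"
NOMATCH_OBSERVATION <- "99999-9"

PLANTED_DATE <- "2021-06-15"
PLANTED_OBS_UNIT <- "mg/dL"
BACKGROUND_DATE_ORIGIN <- as.Date("2019-01-01")
BACKGROUND_DATE_DAYS <- 1826L # five calendar years, 2019-2023

#' Describe the background-data component
#'
#' Resources present in a store that no benchmark query targets, emulating
#' a typical hospital data distribution. Defaults are the built-in
#' background design: 413,375 conditions across 8,593 unique codes, 270,505
#' procedures across 6,429 codes, and 4,907,600 observations across 1,798
#' codes.
#'
#' @param conditions,procedures,observations resource counts.
#' @param conditionCodes,procedureCodes,observationCodes unique-code counts.
#' @return A list of class `fq_background_spec`.
#' @export
background_spec <- function(conditions = 413375, conditionCodes = 8593,
                            procedures = 270505, procedureCodes = 6429,
                            observations = 4907600, observationCodes = 1798) {
  for (v in list(conditions, conditionCodes, procedures, procedureCodes,
                 observations, observationCodes))
    if (!is_count(v)) fq_abort("fq_validation_error",
                               "background counts must be non-negative integers")
  structure(list(conditions = conditions, conditionCodes = conditionCodes,
                 procedures = procedures, procedureCodes = procedureCodes,
                 observations = observations, observationCodes = observationCodes),
            class = "fq_background_spec")
}

#' Benchmark data-set profiles
#'
#' The three built-in profiles:
#' \describe{
#'   \item{small}{planted cohorts of 1,000 / 10,000 / 100,000 patients, no
#'     background: 111,000 patients and 444,000 resources.}
#'   \item{bg-small}{the same cohorts plus the background component:
#'     524,375 conditions, 381,505 procedures, 5,018,600 observations,
#'     6,035,480 resources in total.}
#'   \item{bg-large}{cohorts 1,000 / 10,000 / 100,000 / 1,000,000 plus the
#'     same background: 10,035,480 resources in total.}
#' }
#' A `scale` factor shrinks every cohort and background count
#' proportionally (each scaled count must stay an integer); cohort labels
#' and criterion codes are unaffected, so the benchmark queries of a scaled
#' data set return scaled counts.
#'
#' @param name `"small"`, `"bg-small"`, `"bg-large"`, or `"custom"`.
#' @param cohortSizes integer vector of planted-cohort sizes (custom only).
#' @param background a [background_spec()] or `NULL` (custom only).
#' @param scale positive rational scale factor.
#' @return An object of class `fq_dataset_profile`.
#' @export
dataset_profile <- function(name = c("small", "bg-small", "bg-large", "custom"),
                            cohortSizes = NULL, background = NULL, scale = 1) {
  name <- match.arg(name)
  if (name == "small") {
    cohortSizes <- c(1000, 10000, 100000); background <- NULL
  } else if (name == "bg-small") {
    cohortSizes <- c(1000, 10000, 100000); background <- background_spec()
  } else if (name == "bg-large") {
    cohortSizes <- c(1000, 10000, 100000, 1000000); background <- background_spec()
  } else {
    if (is.null(cohortSizes) || length(cohortSizes) == 0L)
      fq_abort("fq_validation_error", "custom profile requires cohortSizes")
  }
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    fq_abort("fq_validation_error", "scale must be a positive number")
  if (!is.null(background) && !inherits(background, "fq_background_spec"))
    fq_abort("fq_validation_error", "background must be a background_spec()")
  if (anyDuplicated(cohortSizes))
    fq_abort("fq_validation_error", "cohort sizes must be distinct")
  check_int <- function(v, what) {
    scaled <- v * scale
    bad <- abs(scaled - round(scaled)) > 1e-9
    if (any(bad))
      fq_abort("fq_validation_error",
               sprintf("scale %s yields non-integer %s count (%s x %s)",
                       format_decimal(scale), what,
                       format_decimal(v[bad][1]), format_decimal(scale)))
    round(scaled)
  }
  check_int(cohortSizes, "cohort")
  if (!is.null(background))
    for (f in c("conditions", "procedures", "observations"))
      check_int(background[[f]], f)
  structure(list(name = name, cohortSizes = as.numeric(cohortSizes),
                 background = background, scale = scale),
            class = "fq_dataset_profile")
}

# Per-cohort criterion assignment; purely profile-determined (no RNG), so
# benchmark_queries() works without generating the data. With more than
# four cohorts the patient-level criterion switches from administrative
# gender (only four distinct values exist) to a distinct birth-year range
# per cohort.
cohort_table <- function(profile) {
  sizes <- profile$cohortSizes
  k <- length(sizes)
  use_gender <- k <= length(COHORT_GENDERS)
  pick <- function(pool, extra_prefix) {
    if (k <= length(pool)) out <- pool[seq_len(k)]
    else out <- c(pool, sprintf("%s%03d", extra_prefix,
                                seq_len(k - length(pool))))
    out
  }
  cond <- pick(COHORT_CONDITION_CODES, "BMK-C")
  proc <- pick(COHORT_PROCEDURE_CODES, "BMK-P")
  obs <- pick(COHORT_OBSERVATION_CODES, "BMK-O")
  genders <- if (use_gender) COHORT_GENDERS[seq_len(k)]
             else rep(COHORT_GENDERS, length.out = k)
  # the 100,000 cohort carries the female / C50.1 / 5-787 / 55782-7 combination
  target <- which(sizes == 100000)
  if (length(target) == 1L) {
    ref <- which(COHORT_CONDITION_CODES == "C50.1")
    if (target <= length(COHORT_CONDITION_CODES) && target != ref) {
      swap <- function(x) { tmp <- x[target]; x[target] <- x[ref]; x[ref] <- tmp; x }
      cond <- swap(cond); proc <- swap(proc); obs <- swap(obs)
      if (use_gender) genders <- swap(genders)
    }
  }
  data.frame(size = sizes, label = format(sizes, scientific = FALSE, trim = TRUE),
             gender = genders, birthYear = 1950L + seq_len(k),
             conditionCode = cond, procedureCode = proc,
             observationCode = obs,
             observationValue = 20 + seq_len(k),
             patientCriterion = if (use_gender) "gender" else "birthdate",
             stringsAsFactors = FALSE)
}

#' Terminology tree and mapping table for a profile's benchmark codes
#'
#' Builds the flat terminology forest (the benchmark codes have no
#' hierarchy) and the mapping table covering all cohort criterion codes,
#' the patient-attribute concepts, and the no-match codes.
#'
#' @param profile an [dataset_profile()].
#' @return List with elements `tree` (`fq_term_tree`) and `mapping`
#'   (`fq_mapping_table`).
#' @export
dataset_terminology <- function(profile) {
  stopifnot(inherits(profile, "fq_dataset_profile"))
  ct <- cohort_table(profile)
  leaf <- function(tc) list(termCode = tc, children = list())
  cond_codes <- c(ct$conditionCode, NOMATCH_CONDITION)
  proc_codes <- c(ct$procedureCode, NOMATCH_PROCEDURE)
  obs_codes <- c(ct$observationCode, NOMATCH_OBSERVATION)
  roots <- c(
    lapply(cond_codes, function(cd) leaf(term_code(ICD10_SYSTEM, cd))),
    lapply(proc_codes, function(cd) leaf(term_code(OPS_SYSTEM, cd))),
    lapply(obs_codes, function(cd) leaf(term_code(LOINC_SYSTEM, cd))),
    list(leaf(GENDER_CONCEPT()), leaf(BIRTHDATE_CONCEPT())))
  entries <- c(
    lapply(cond_codes, function(cd)
      mapping_entry(term_code(ICD10_SYSTEM, cd), "Condition",
                    termCodeSearchParameter = "code",
                    timeRestrictionParameter = "recorded-date")),
    lapply(proc_codes, function(cd)
      mapping_entry(term_code(OPS_SYSTEM, cd), "Procedure",
                    termCodeSearchParameter = "code",
                    timeRestrictionParameter = "date")),
    lapply(obs_codes, function(cd)
      mapping_entry(term_code(LOINC_SYSTEM, cd), "Observation",
                    termCodeSearchParameter = "code",
                    valueSearchParameter = "value-quantity",
                    timeRestrictionParameter = "date")),
    list(mapping_entry(GENDER_CONCEPT(), "Patient",
                       valueSearchParameter = "gender"),
         mapping_entry(BIRTHDATE_CONCEPT(), "Patient",
                       timeRestrictionParameter = "birthdate")))
  list(tree = term_tree(roots), mapping = mapping_table(entries))
}

cohort_patient_criterion <- function(ct, i) {
  if (ct$patientCriterion[i] == "gender")
    criterion(GENDER_CONCEPT(),
              valueFilter = value_filter(
                "concept",
                selectedConcepts = list(term_code(ADMIN_GENDER_SYSTEM,
                                                  ct$gender[i]))))
  else
    criterion(BIRTHDATE_CONCEPT(),
              timeRestriction = time_restriction(
                afterDate = sprintf("%d-01-01", ct$birthYear[i]),
                beforeDate = sprintf("%d-12-31", ct$birthYear[i])))
}

#' Generate only the background-data component
#'
#' Background resources are attached round-robin to the supplied patients
#' and spread over the specified number of unique codes with sizes as equal
#' as possible (code of resource j is `j mod k`). Background codes carry a
#' `BG-` prefix, disjoint by construction from every benchmark criterion
#' code. Dates are uniform over a fixed five-year window and observation
#' values uniform in (0, 100], both drawn from the seeded RNG.
#'
#' @param bg a [background_spec()] (counts taken as given, i.e. already
#'   scaled if scaling is wanted).
#' @param patient_ids character vector of patient ids to attach to.
#' @param seed integer RNG seed.
#' @return List of clinical tables `conditions`, `procedures`,
#'   `observations` in the column layout of [resource_store()].
#' @export
generate_background <- function(bg, patient_ids, seed = 1) {
  stopifnot(inherits(bg, "fq_background_spec"), length(patient_ids) > 0L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  date_pool <- as.character(BACKGROUND_DATE_ORIGIN +
                              seq_len(BACKGROUND_DATE_DAYS) - 1L)
  make <- function(n, k, system, code_prefix, id_prefix, with_value) {
    if (n == 0L) {
      df <- empty_clinical(if (with_value) "Observation" else "Condition")
      return(df)
    }
    j <- seq_len(n) - 1L
    df <- data.frame(
      id = paste0(id_prefix, j + 1L),
      system = system,
      code = sprintf("%s%05d", code_prefix, (j %% k) + 1L),
      subject = patient_ids[(j %% length(patient_ids)) + 1L],
      date = date_pool[sample.int(BACKGROUND_DATE_DAYS, n, replace = TRUE)],
      stringsAsFactors = FALSE)
    if (with_value) {
      df$value <- round(runif(n, 0, 100), 1)
      df$unit <- PLANTED_OBS_UNIT
      df$valueSystem <- UCUM_SYSTEM
    }
    df
  }
  list(
    conditions = make(bg$conditions, bg$conditionCodes, ICD10_SYSTEM,
                      "BG-C", "c-bg-", FALSE),
    procedures = make(bg$procedures, bg$procedureCodes, OPS_SYSTEM,
                      "BG-P", "pr-bg-", FALSE),
    observations = make(bg$observations, bg$observationCodes, LOINC_SYSTEM,
                        "BG-O", "o-bg-", TRUE))
}

#' Generate a benchmark data set
#'
#' Builds the resource store of the profile: one patient block per planted
#' cohort (every member carrying the cohort's patient attribute plus one
#' matching Condition, Procedure and Observation, and nothing matching any
#' other cohort's criteria), followed by the background component if the
#' profile has one. Deterministic: the same profile and seed produce an
#' identical store (and byte-identical NDJSON via [write_dataset()]).
#'
#' @param profile an [dataset_profile()].
#' @param seed integer RNG seed (only background dates/values consume
#'   randomness).
#' @return An object of class `fq_dataset`: list with `store`
#'   (`fq_resource_store`), `profile`, `cohorts` (assignment table), `tree`,
#'   `mapping`, and `manifest` (realized counts).
#' @export
generate_dataset <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "fq_dataset_profile"))
  ct <- cohort_table(profile)
  sizes <- as.integer(round(profile$cohortSizes * profile$scale))
  n_pat <- sum(sizes)
  cohort_of <- rep(seq_along(sizes), sizes)
  patients <- data.frame(
    id = sprintf("p-%07d", seq_len(n_pat)),
    gender = ct$gender[cohort_of],
    birthDate = sprintf("%d-06-15", ct$birthYear[cohort_of]),
    stringsAsFactors = FALSE)
  conditions <- data.frame(
    id = sprintf("c-%07d", seq_len(n_pat)),
    system = ICD10_SYSTEM, code = ct$conditionCode[cohort_of],
    subject = patients$id, date = PLANTED_DATE, stringsAsFactors = FALSE)
  procedures <- data.frame(
    id = sprintf("pr-%07d", seq_len(n_pat)),
    system = OPS_SYSTEM, code = ct$procedureCode[cohort_of],
    subject = patients$id, date = PLANTED_DATE, stringsAsFactors = FALSE)
  observations <- data.frame(
    id = sprintf("o-%07d", seq_len(n_pat)),
    system = LOINC_SYSTEM, code = ct$observationCode[cohort_of],
    subject = patients$id, date = PLANTED_DATE,
    value = ct$observationValue[cohort_of], unit = PLANTED_OBS_UNIT,
    valueSystem = UCUM_SYSTEM, stringsAsFactors = FALSE)

  if (!is.null(profile$background)) {
    bg_spec <- profile$background
    scaled_bg <- background_spec(
      conditions = round(bg_spec$conditions * profile$scale),
      conditionCodes = bg_spec$conditionCodes,
      procedures = round(bg_spec$procedures * profile$scale),
      procedureCodes = bg_spec$procedureCodes,
      observations = round(bg_spec$observations * profile$scale),
      observationCodes = bg_spec$observationCodes)
    bg <- generate_background(scaled_bg, patients$id, seed = seed)
    conditions <- rbind(conditions, bg$conditions)
    procedures <- rbind(procedures, bg$procedures)
    observations <- rbind(observations, bg$observations)
  }

  store <- resource_store(patients, conditions, procedures, observations)
  term <- dataset_terminology(profile)
  census <- store_census(store)
  manifest <- list(
    profile = profile$name, scale = profile$scale, seed = seed,
    counts = as.list(census),
    cohorts = lapply(seq_len(nrow(ct)), function(i) list(
      label = ct$label[i], size = sizes[i],
      patientCriterion = ct$patientCriterion[i],
      gender = ct$gender[i], birthYear = ct$birthYear[i],
      conditionCode = ct$conditionCode[i],
      procedureCode = ct$procedureCode[i],
      observationCode = ct$observationCode[i])))
  structure(list(store = store, profile = profile, cohorts = ct,
                 tree = term$tree, mapping = term$mapping,
                 manifest = manifest),
            class = "fq_dataset")
}

#' @export
print.fq_dataset <- function(x, ...) {
  cat(sprintf("<benchmark data set> profile '%s', scale %s, %d cohort(s)\n",
              x$profile$name, format_decimal(x$profile$scale), nrow(x$cohorts)))
  print(x$store)
  invisible(x)
}

#' The benchmark query suite of a profile
#'
#' Two queries per planted cohort — `<N>-1` (the cohort's single condition
#' criterion) and `<N>-all` (the AND of its patient, condition, procedure
#' and observation criteria, each as its own inclusion group) — plus one
#' four-criterion no-match query labeled `0` whose codes occur nowhere in
#' the data. On the generated store, `<N>-1` and `<N>-all` return exactly
#' the (scaled) cohort size, `<N>-all` processing four resources per
#' matching patient, and `0` returns zero processing zero resources.
#'
#' @param profile an [dataset_profile()].
#' @return Named list of [structured_query()] objects; names are the labels.
#' @export
benchmark_queries <- function(profile) {
  stopifnot(inherits(profile, "fq_dataset_profile"))
  ct <- cohort_table(profile)
  out <- list()
  for (i in seq_len(nrow(ct))) {
    cond <- criterion(term_code(ICD10_SYSTEM, ct$conditionCode[i]))
    proc <- criterion(term_code(OPS_SYSTEM, ct$procedureCode[i]))
    obs <- criterion(term_code(LOINC_SYSTEM, ct$observationCode[i]))
    pat <- cohort_patient_criterion(ct, i)
    out[[paste0(ct$label[i], "-1")]] <-
      structured_query(inclusionCriteria = list(list(cond)))
    out[[paste0(ct$label[i], "-all")]] <-
      structured_query(inclusionCriteria = list(list(pat), list(cond),
                                                list(proc), list(obs)))
  }
  nomatch_pat <- criterion(BIRTHDATE_CONCEPT(),
                           timeRestriction = time_restriction(
                             afterDate = "1900-01-01",
                             beforeDate = "1900-12-31"))
  out[["0"]] <- structured_query(inclusionCriteria = list(
    list(nomatch_pat),
    list(criterion(term_code(ICD10_SYSTEM, NOMATCH_CONDITION))),
    list(criterion(term_code(OPS_SYSTEM, NOMATCH_PROCEDURE))),
    list(criterion(term_code(LOINC_SYSTEM, NOMATCH_OBSERVATION)))))
  out
}

#' Write a generated data set to disk
#'
#' Writes the resources as NDJSON (combined, or one file per resource
#' type), the terminology tree and mapping files, and a manifest JSON with
#' the realized counts and cohort code assignments. Equal data sets produce
#' byte-identical files.
#'
#' @param ds an [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @param split one NDJSON per resource type instead of a combined file.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, split = FALSE) {
  stopifnot(inherits(ds, "fq_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (split) {
    for (type in STORE_TYPES) {
      sub <- ds$store
      for (other in setdiff(STORE_TYPES, type))
        sub[[other]] <- sub[[other]][0, , drop = FALSE]
      write_store(sub, file.path(dir, paste0(tolower(type), ".ndjson")))
    }
  } else {
    write_store(ds$store, file.path(dir, "resources.ndjson"))
  }
  writeLines(serialize_term_tree(ds$tree), file.path(dir, "term-tree.json"))
  writeLines(serialize_mapping_table(ds$mapping), file.path(dir, "mapping.json"))
  writeLines(as.character(jsonlite::toJSON(ds$manifest, auto_unbox = TRUE,
                                           digits = NA)),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
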
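# Shared fixtures and independent oracles for the test suite.
# Everything here is built in code; the oracles deliberately avoid the code
# paths they verify.

ICD <- "http://fhir.de/CodeSystem/bfarm/icd-10-gm"
OPS <- "http://fhir.de/CodeSystem/bfarm/ops"
LOINC <- "http://loinc.org"
SNOMED <- "http://snomed.info/sct"
GENDER_SYS <- "http://hl7.org/fhir/administrative-gender"
UCUM <- "http://unitsofmeasure.org"

toy_tree_path <- function() {
  system.file("extdata", "term-tree-toy.json", package = "feasquery")
}
toy_mapping_path <- function() {
  system.file("extdata", "mapping-toy.json", package = "feasquery")
}
toy_tree <- function() read_term_tree(toy_tree_path())
toy_mapping <- function() read_mapping_table(toy_mapping_path())

gender_criterion <- function(code = "female") {
  criterion(term_code(SNOMED, "263495000", "Gender"),
            valueFilter = value_filter("concept", selectedConcepts = list(
              term_code(GENDER_SYS, code))))
}

# ---- random store + query generation --------------------------------------

# Small pool of concepts with known store columns; used for the randomized
# executor-vs-oracle property.
concept_pool <- function() {
  list(
    list(kind = "Condition", tc = term_code(ICD, "A01")),
    list(kind = "Condition", tc = term_code(ICD, "A02")),
    list(kind = "Condition", tc = term_code(ICD, "A03")),
    list(kind = "Procedure", tc = term_code(OPS, "P01")),
    list(kind = "Procedure", tc = term_code(OPS, "P02")),
    list(kind = "Observation", tc = term_code(LOINC, "L01")),
    list(kind = "Observation", tc = term_code(LOINC, "L02")),
    list(kind = "Patient", tc = NULL))
}

pool_terminology <- function() {
  pool <- concept_pool()
  leaf <- function(tc) list(termCode = tc, children = list())
  roots <- list(leaf(term_code(SNOMED, "263495000")))
  entries <- list(mapping_entry(term_code(SNOMED, "263495000"), "Patient",
                                valueSearchParameter = "gender"))
  for (p in pool) {
    if (p$kind == "Patient") next
    roots <- c(roots, list(leaf(p$tc)))
    entries <- c(entries, list(switch(p$kind,
      Condition = mapping_entry(p$tc, "Condition",
                                termCodeSearchParameter = "code",
                                timeRestrictionParameter = "recorded-date"),
      Procedure = mapping_entry(p$tc, "Procedure",
                                termCodeSearchParameter = "code",
                                timeRestrictionParameter = "date"),
      Observation = mapping_entry(p$tc, "Observation",
                                  termCodeSearchParameter = "code",
                                  valueSearchParameter = "value-quantity",
                                  timeRestrictionParameter = "date"))))
  }
  list(tree = term_tree(roots), mapping = mapping_table(entries))
}

# random criterion over the pool; optionally with value/time filters
random_criterion <- function() {
  pool <- concept_pool()
  p <- pool[[sample.int(length(pool), 1)]]
  if (p$kind == "Patient")
    return(gender_criterion(sample(c("female", "male", "other"), 1)))
  tr <- NULL
  if (runif(1) < 0.3)
    tr <- time_restriction(afterDate = "2020-01-01", beforeDate = "2021-12-31")
  vf <- NULL
  if (p$kind == "Observation" && runif(1) < 0.4) {
    if (runif(1) < 0.5)
      vf <- value_filter("quantity-comparator",
                         comparator = sample(c("gt", "ge", "lt", "le"), 1),
                         value = round(runif(1, 20, 80)), unit = "mg/dL")
    else
      vf <- value_filter("quantity-range", minValue = 20, maxValue = 60,
                         unit = "mg/dL")
  }
  criterion(p$tc, valueFilter = vf, timeRestriction = tr)
}

random_query <- function(max_incl = 3, max_excl = 2) {
  n_incl <- sample.int(max_incl, 1)
  incl <- lapply(seq_len(n_incl), function(i)
    lapply(seq_len(sample.int(2, 1)), function(j) random_criterion()))
  n_excl <- sample.int(max_excl + 1, 1) - 1L
  excl <- lapply(seq_len(n_excl), function(i)
    lapply(seq_len(sample.int(2, 1)), function(j) random_criterion()))
  structured_query(inclusionCriteria = incl, exclusionCriteria = excl)
}

random_store <- function(n_patients = 12) {
  genders <- sample(c("female", "male", "other"), n_patients, replace = TRUE)
  pid <- sprintf("pat-%02d", seq_len(n_patients))
  patients <- data.frame(id = pid, gender = genders,
                         birthDate = "1980-05-01", stringsAsFactors = FALSE)
  rand_dates <- function(n) as.character(as.Date("2019-06-01") +
                                           sample.int(1200, n, replace = TRUE))
  mk_clin <- function(prefix, system, codes, n) {
    data.frame(id = sprintf("%s-%03d", prefix, seq_len(n)),
               system = system,
               code = sample(codes, n, replace = TRUE),
               subject = sample(pid, n, replace = TRUE),
               date = rand_dates(n), stringsAsFactors = FALSE)
  }
  n_cond <- sample.int(20, 1); n_proc <- sample.int(10, 1)
  n_obs <- sample.int(15, 1)
  obs <- mk_clin("obs", LOINC, c("L01", "L02"), n_obs)
  obs$value <- round(runif(n_obs, 0, 100)); obs$unit <- "mg/dL"
  obs$valueSystem <- UCUM
  resource_store(
    patients = patients,
    conditions = mk_clin("cond", ICD, c("A01", "A02", "A03"), n_cond),
    procedures = mk_clin("proc", OPS, c("P01", "P02"), n_proc),
    observations = obs)
}

# ---- independent oracles ---------------------------------------------------

# per-criterion satisfied-patient set by direct store scan (no search URLs,
# no translator); implements the criterion semantics from first principles
oracle_criterion_patients <- function(store, crit) {
  tc <- crit$termCodes[[1]]
  in_window <- function(dates) {
    ok <- rep(TRUE, length(dates))
    tr <- crit$timeRestriction
    if (is.null(tr)) return(ok)
    d <- as.Date(dates)
    if (!is.null(tr$afterDate)) ok <- ok & d >= as.Date(tr$afterDate)
    if (!is.null(tr$beforeDate)) ok <- ok & d <= as.Date(tr$beforeDate)
    ok & !is.na(d)
  }
  if (identical(tc$system, SNOMED) && identical(tc$code, "263495000")) {
    wanted <- vapply(crit$valueFilter$selectedConcepts, function(x) x$code,
                     character(1))
    return(store$Patient$id[store$Patient$gender %in% wanted])
  }
  if (identical(tc$system, SNOMED) && identical(tc$code, "184099003")) {
    return(store$Patient$id[in_window(store$Patient$birthDate)])
  }
  type <- switch(tc$system, `http://fhir.de/CodeSystem/bfarm/icd-10-gm` = "Condition",
                 `http://fhir.de/CodeSystem/bfarm/ops` = "Procedure",
                 `http://loinc.org` = "Observation")
  df <- store[[type]]
  ok <- df$system == tc$system & df$code == tc$code & in_window(df$date)
  vf <- crit$valueFilter
  if (!is.null(vf)) {
    if (vf$kind == "quantity-comparator") {
      cmp <- switch(vf$comparator, gt = `>`, ge = `>=`, lt = `<`,
                    le = `<=`, eq = `==`)
      ok <- ok & cmp(df$value, vf$value) & df$unit == vf$unit &
        df$valueSystem == UCUM
    } else if (vf$kind == "quantity-range") {
      ok <- ok & df$value >= vf$minValue & df$value <= vf$maxValue &
        df$unit == vf$unit & df$valueSystem == UCUM
    }
  }
  unique(df$subject[ok & !is.na(ok)])
}

# truth assignments for all criteria of a query, keyed by criterion_key
oracle_patient_facts <- function(store, q) {
  crits <- query_criteria(q)
  keys <- vapply(crits, criterion_key, character(1))
  sat <- lapply(crits, oracle_criterion_patients, store = store)
  facts <- lapply(store$Patient$id, function(pid)
    keys[vapply(sat, function(s) pid %in% s, logical(1))])
  stats::setNames(facts, store$Patient$id)
}

# independent CNF/DNF evaluation via a constructed boolean R expression
oracle_boolean_eval <- function(q, sat) {
  # sat: named logical vector per criterion index "x1", "x2", ...
  crits <- query_criteria(q)
  n_incl <- sum(lengths(q$inclusionCriteria))
  idx <- 0L
  grp <- function(g, op) {
    refs <- sprintf("x%d", idx + seq_along(g))
    idx <<- idx + length(g)
    paste0("(", paste(refs, collapse = op), ")")
  }
  incl <- paste(vapply(q$inclusionCriteria, grp, character(1), op = "||"),
                collapse = "&&")
  expr <- incl
  if (length(q$exclusionCriteria)) {
    excl <- paste(vapply(q$exclusionCriteria, grp, character(1), op = "&&"),
                  collapse = "||")
    expr <- paste0("(", incl, ") && !(", excl, ")")
  }
  eval(parse(text = expr), envir = as.list(sat))
}

# ---- tiny CQL boolean-skeleton parser (independent of the generator) ------

# Parses the InInitialPopulation expression (identifiers, and/or/not,
# parentheses) into an evaluable R call; precedence: not > and > or.
cql_skeleton_parse <- function(text) {
  tokens <- regmatches(text, gregexpr("[A-Za-z_][A-Za-z_0-9]*|\\(|\\)", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    while (identical(peek(), "or")) { take(); left <- call("||", left, parse_and()) }
    left
  }
  parse_and <- function() {
    left <- parse_not()
    while (identical(peek(), "and")) { take(); left <- call("&&", left, parse_not()) }
    left
  }
  parse_not <- function() {
    if (identical(peek(), "not")) { take(); return(call("!", parse_not())) }
    parse_primary()
  }
  parse_primary <- function() {
    t <- take()
    if (identical(t, "(")) {
      inner <- parse_or()
      if (!identical(take(), ")")) stop("unbalanced parentheses")
      return(inner)
    }
    if (is.na(t) || t %in% c("and", "or", "not", ")"))
      stop(sprintf("unexpected token '%s'", t))
    as.name(t)
  }
  out <- parse_or()
  if (pos <= length(tokens)) stop("trailing tokens in boolean expression")
  out
}

# extract the InInitialPopulation expression text from generated CQL
cql_population_text <- function(cql) {
  m <- regmatches(cql, regexpr("define InInitialPopulation:\n.*", cql))
  sub("define InInitialPopulation:\n", "", m, fixed = TRUE)
}

# structural CQL checks written independently of the generator
cql_grammar_check <- function(cql) {
  lines <- strsplit(cql, "\n", fixed = TRUE)[[1]]
  stopifnot(grepl("^library [A-Za-z_][A-Za-z_0-9]* version '", lines[1]))
  stopifnot(any(grepl("^using FHIR version '", lines)))
  # balanced parentheses and quotes over the whole text
  chars <- strsplit(cql, "")[[1]]
  depth <- 0
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    stopifnot(depth >= 0)
  }
  stopifnot(depth == 0)
  stopifnot(sum(chars == "'") %% 2 == 0)
  # every alias used in a retrieve is declared before use
  decls <- regmatches(cql, gregexpr("codesystem (cs[0-9]+):", cql))[[1]]
  declared <- sub("codesystem (cs[0-9]+):.*", "\\1", decls)
  used <- unique(regmatches(cql, gregexpr("from (cs[0-9]+)", cql))[[1]])
  used <- sub("from ", "", used)
  stopifnot(all(used %in% declared))
  stopifnot(!anyDuplicated(declared))
  # population expression parses with correct arity
  expr <- cql_skeleton_parse(cql_population_text(cql))
  stopifnot(is.call(expr) || is.name(expr))
  invisible(TRUE)
}
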
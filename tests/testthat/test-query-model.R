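test_that("a minimal query document parses into one group with one criterion", {
  doc <- '{
    "version": "fq/v1",
    "inclusionCriteria": [[{"termCodes": [
      {"system": "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
       "code": "E11", "display": "Diabetes mellitus, Type 2"}]}]]
  }'
  q <- parse_structured_query(doc)
  expect_s3_class(q, "fq_structured_query")
  expect_length(q$inclusionCriteria, 1)
  expect_length(q$inclusionCriteria[[1]], 1)
  expect_length(q$exclusionCriteria, 0)
  expect_equal(q$inclusionCriteria[[1]][[1]]$termCodes[[1]]$code, "E11")
})

test_that("invariant violations and malformed documents are rejected", {
  expect_error(parse_structured_query("{not json"), class = "fq_parse_error")
  expect_error(parse_structured_query('{"version":"v","inclusionCriteria":[]}'),
               class = "fq_validation_error")
  expect_error(parse_structured_query('{"version":"v"}'),
               class = "fq_validation_error")
  # unknown fields are rejected with the field path in the message
  bad <- '{"version":"v","inclusionCriteria":[[{"termCodes":[{"system":"s","code":"c"}],"bogus":1}]]}'
  err <- expect_error(parse_structured_query(bad), class = "fq_validation_error")
  expect_match(conditionMessage(err), "bogus")
  expect_match(conditionMessage(err), "inclusionCriteria\\[1\\]\\[1\\]")
  # unknown valueFilter kind
  vf <- '{"version":"v","inclusionCriteria":[[{"termCodes":[{"system":"s","code":"c"}],
        "valueFilter":{"type":"regex"}}]]}'
  expect_error(parse_structured_query(vf), class = "fq_validation_error")
  # empty group
  expect_error(parse_structured_query('{"version":"v","inclusionCriteria":[[]]}'),
               class = "fq_validation_error")
})

test_that("constructors enforce the domain invariants", {
  expect_error(term_code("", "x"), class = "fq_validation_error")
  expect_error(term_code("s", ""), class = "fq_validation_error")
  expect_error(value_filter("concept", selectedConcepts = list()),
               class = "fq_validation_error")
  expect_error(value_filter("quantity-range", minValue = 5, maxValue = 1,
                            unit = "mg/dL"),
               class = "fq_validation_error")
  expect_error(value_filter("quantity-comparator", comparator = "ne",
                            value = 1, unit = "mg/dL"),
               class = "fq_validation_error")
  # fields of another kind must be absent
  expect_error(value_filter("concept",
                            selectedConcepts = list(term_code("s", "c")),
                            value = 3),
               class = "fq_validation_error")
  expect_error(time_restriction(), class = "fq_validation_error")
  expect_error(time_restriction("2021-01-01", "2020-01-01"),
               class = "fq_validation_error")
  expect_error(criterion(list()), class = "fq_validation_error")
  expect_error(structured_query(list()), class = "fq_validation_error")
})

test_that("serialization is canonical and round-trips, ignoring displays", {
  tc <- term_code(ICD, "E11", "Diabetes mellitus, Type 2")
  q <- structured_query(
    inclusionCriteria = list(list(criterion(tc)), list(gender_criterion())),
    exclusionCriteria = list(list(criterion(term_code(LOINC, "2160-0"),
      valueFilter = value_filter("quantity-comparator", comparator = "gt",
                                 value = 1.5, unit = "mg/dL")))))
  j1 <- serialize_structured_query(q)
  j2 <- serialize_structured_query(q)
  expect_identical(j1, j2)                       # byte-identical across runs
  expect_true(sq_equal(parse_structured_query(j1), q))
  # displays differing only: serializations differ, identity equality holds
  q2 <- q
  q2$inclusionCriteria[[1]][[1]]$termCodes[[1]]$display <- "Other display"
  expect_false(identical(serialize_structured_query(q2), j1))
  expect_true(sq_equal(q2, q))
})

test_that("parse/serialize is the identity on a corpus of random queries", {
  set.seed(42)
  for (i in 1:60) {
    q <- random_query()
    j <- serialize_structured_query(q)
    q2 <- parse_structured_query(j)
    expect_true(sq_equal(q, q2))
    expect_identical(serialize_structured_query(q2), j)
  }
})

test_that("all value-filter kinds and time restrictions survive a round trip", {
  crits <- list(
    criterion(term_code(LOINC, "2160-0"),
              valueFilter = value_filter("concept", selectedConcepts = list(
                term_code(SNOMED, "260385009", "Negative")))),
    criterion(term_code(LOINC, "2160-0"),
              valueFilter = value_filter("quantity-comparator",
                                         comparator = "le", value = 2.5,
                                         unit = "mg/dL")),
    criterion(term_code(LOINC, "2160-0"),
              valueFilter = value_filter("quantity-range", minValue = 1,
                                         maxValue = 2, unit = "mg/dL"),
              timeRestriction = time_restriction("2020-01-01", "2021-12-31")))
  q <- structured_query(inclusionCriteria = list(crits))
  expect_true(sq_equal(parse_structured_query(serialize_structured_query(q)), q))
})

test_that("reference evaluation implements the CNF/DNF contract", {
  A <- criterion(term_code("s", "A")); B <- criterion(term_code("s", "B"))
  kA <- criterion_key(A); kB <- criterion_key(B)
  facts <- list(p1 = c(kA), p2 = c(kB), p3 = c(kA, kB), p4 = character(0))

  qA <- structured_query(inclusionCriteria = list(list(A)))
  expect_setequal(evaluate_reference(qA, facts), c("p1", "p3"))

  # inclusion {{A}}, exclusion {{A}} -> empty for all inputs
  qAA <- structured_query(inclusionCriteria = list(list(A)),
                          exclusionCriteria = list(list(A)))
  expect_length(evaluate_reference(qAA, facts), 0)

  # De Morgan: {{A},{B}} = A intersect B; {{A,B}} = A union B
  q_and <- structured_query(inclusionCriteria = list(list(A), list(B)))
  expect_setequal(evaluate_reference(q_and, facts), "p3")
  q_or <- structured_query(inclusionCriteria = list(list(A, B)))
  expect_setequal(evaluate_reference(q_or, facts), c("p1", "p2", "p3"))
})

test_that("reference evaluation equals truth-table enumeration on random queries", {
  set.seed(7)
  crits <- lapply(c("A", "B", "C"), function(cd) criterion(term_code("s", cd)))
  keys <- vapply(crits, criterion_key, character(1))
  for (rep in 1:40) {
    pick_groups <- function(n_groups) {
      lapply(seq_len(n_groups), function(i) {
        members <- sample.int(3, sample.int(2, 1))
        lapply(members, function(m) crits[[m]])
      })
    }
    q <- structured_query(inclusionCriteria = pick_groups(sample.int(2, 1)),
                          exclusionCriteria = pick_groups(sample.int(2, 1) - 1L))
    # 50 random patients with random truth assignments over A, B, C
    sat_mat <- matrix(sample(c(TRUE, FALSE), 50 * 3, replace = TRUE), ncol = 3)
    facts <- setNames(lapply(seq_len(50), function(p) keys[sat_mat[p, ]]),
                      sprintf("p%02d", 1:50))
    got <- evaluate_reference(q, facts)
    # independent route: boolean expression evaluated per assignment, where
    # x1..xk follow the query's criterion document order
    crit_order <- vapply(query_criteria(q), criterion_key, character(1))
    expected <- names(facts)[vapply(seq_len(50), function(p) {
      sat <- setNames(crit_order %in% keys[sat_mat[p, ]],
                      sprintf("x%d", seq_along(crit_order)))
      oracle_boolean_eval(q, sat)
    }, logical(1))]
    expect_setequal(got, expected)
  }
})

test_that("adding groups never enlarges the reference result set", {
  set.seed(11)
  A <- criterion(term_code("s", "A")); B <- criterion(term_code("s", "B"))
  keys <- c(criterion_key(A), criterion_key(B))
  for (rep in 1:20) {
    facts <- setNames(lapply(1:30, function(p)
      keys[sample(c(TRUE, FALSE), 2, replace = TRUE)]), sprintf("p%02d", 1:30))
    base <- structured_query(inclusionCriteria = list(list(A)))
    more_incl <- structured_query(inclusionCriteria = list(list(A), list(B)))
    with_excl <- structured_query(inclusionCriteria = list(list(A)),
                                  exclusionCriteria = list(list(B)))
    r0 <- evaluate_reference(base, facts)
    expect_true(all(evaluate_reference(more_incl, facts) %in% r0))
    expect_true(all(evaluate_reference(with_excl, facts) %in% r0))
  }
})
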
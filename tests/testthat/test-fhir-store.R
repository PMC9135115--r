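ndjson_fixture <- function(dir = NULL) {
  if (is.null(dir)) { dir <- tempfile("fx"); dir.create(dir) }
  lines <- c(
    '{"resourceType":"Patient","id":"p1","gender":"female","birthDate":"1980-01-01"}',
    '{"resourceType":"Patient","id":"p2","gender":"female","birthDate":"1990-06-15"}',
    '{"resourceType":"Patient","id":"p3","gender":"male","birthDate":"1975-12-31"}',
    paste0('{"resourceType":"Condition","id":"c1","code":{"coding":[{"system":"', ICD,
           '","code":"C50.1"}]},"subject":{"reference":"Patient/p1"},"recordedDate":"2021-03-01"}'),
    paste0('{"resourceType":"Condition","id":"c2","code":{"coding":[{"system":"', ICD,
           '","code":"E11.0"},{"system":"', ICD,
           '","code":"E11"}]},"subject":{"reference":"Patient/p2"},"recordedDate":"2019-07-12"}'),
    paste0('{"resourceType":"Observation","id":"o1","code":{"coding":[{"system":"', LOINC,
           '","code":"2160-0"}]},"subject":{"reference":"Patient/p1"},"effectiveDateTime":"2021-05-20",',
           '"valueQuantity":{"value":2.4,"unit":"mg/dL","system":"', UCUM, '","code":"mg/dL"}}'),
    paste0('{"resourceType":"Observation","id":"o2","code":{"coding":[{"system":"', LOINC,
           '","code":"2160-0"}]},"subject":{"reference":"Patient/p3"},"effectiveDateTime":"2020-01-02",',
           '"valueQuantity":{"value":1.1,"unit":"mg/dL","system":"', UCUM, '","code":"mg/dL"}}'))
  path <- file.path(dir, "resources.ndjson")
  writeLines(lines, path)
  path
}

test_that("NDJSON loading indexes resources and counts per type", {
  store <- read_store(ndjson_fixture())
  census <- store_census(store)
  expect_equal(unname(census[c("Patient", "Condition", "Observation")]),
               c(3, 2, 2))
  expect_equal(unname(census["Total"]), 7)
})

test_that("a collection Bundle loads to the same store as equivalent NDJSON", {
  dir <- withr::local_tempdir()
  path <- ndjson_fixture(dir)
  store1 <- read_store(path)
  bundle_path <- file.path(dir, "bundle.json")
  write_store(store1, bundle_path, format = "bundle")
  store2 <- read_store(bundle_path, format = "bundle")
  expect_equal(store_census(store2), store_census(store1))
  expect_setequal(store2$Patient$id, store1$Patient$id)
  expect_setequal(store2$Condition$id, store1$Condition$id)
})

test_that("empty files yield an empty store and unknown types are skipped", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.ndjson")
  file.create(empty)
  expect_equal(unname(store_census(read_store(empty))["Total"]), 0)
  odd <- file.path(dir, "odd.ndjson")
  writeLines(c('{"resourceType":"Medication","id":"m1"}',
               '{"resourceType":"Patient","id":"p1","gender":"other","birthDate":"2000-01-01"}'),
             odd)
  expect_warning(store <- read_store(odd), "Medication")
  expect_equal(unname(store_census(store)["Patient"]), 1)
})

test_that("dangling subject references fail unless lenient", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dangling.ndjson")
  writeLines(paste0('{"resourceType":"Condition","id":"c1","code":{"coding":[{"system":"s","code":"x"}]},',
                    '"subject":{"reference":"Patient/ghost"},"recordedDate":"2021-01-01"}'),
             path)
  expect_error(read_store(path), class = "fq_validation_error")
  store <- read_store(path, lenient = TRUE)
  expect_equal(unname(store_census(store)["Condition"]), 1)
})

test_that("token, comma-OR, quantity and date search semantics hold", {
  store <- read_store(ndjson_fixture())
  # Patient?gender=female
  fem <- store_search(store, "Patient?gender=female")
  expect_setequal(fem$id, c("p1", "p2"))
  # comma token OR: union of matches
  both <- store_search(store, sprintf("Condition?code=%s|C50.1,%s|E11",
                                      ICD, ICD))
  expect_setequal(both$id, c("c1", "c2"))
  # bare code matches any system
  expect_equal(store_search(store, "Condition?code=C50.1")$id, "c1")
  # multi-coding resource matches through either coding but counts once
  expect_equal(store_search(store, sprintf("Condition?code=%s|E11.0,%s|E11",
                                           ICD, ICD))$id, "c2")
  # quantity with unit/system in the token
  hi <- store_search(store, sprintf("Observation?code=%s|2160-0&value-quantity=gt2|%s|mg/dL",
                                    LOINC, utils::URLencode(UCUM, reserved = TRUE)))
  expect_equal(hi$id, "o1")
  # date ge/le inclusive at day precision
  expect_equal(store_search(store, "Condition?recorded-date=ge2021-03-01")$id, "c1")
  expect_setequal(store_search(store, "Condition?recorded-date=le2021-03-01")$id,
                  c("c1", "c2"))
})

test_that("search equals a brute-force scan on random stores and is pure", {
  set.seed(17)
  for (rep in 1:25) {
    store <- random_store()
    before <- store_census(store)
    cmp <- sample(c("gt", "ge", "lt", "le"), 1)
    thr <- round(runif(1, 10, 90))
    url <- sprintf("Observation?code=%s|L01&value-quantity=%s%d|%s|mg/dL",
                   LOINC, cmp, thr, utils::URLencode(UCUM, reserved = TRUE))
    got <- store_search(store, url)
    f <- switch(cmp, gt = `>`, ge = `>=`, lt = `<`, le = `<=`)
    df <- store$Observation
    expected <- df$id[df$code == "L01" & df$system == LOINC &
                        f(df$value, thr) & df$unit == "mg/dL"]
    expect_setequal(got$id, expected)
    # repeated calls identical, store unchanged
    expect_identical(store_search(store, url)$id, got$id)
    expect_identical(store_census(store), before)
  }
})

test_that("unsupported parameters raise a named error instead of being ignored", {
  store <- read_store(ndjson_fixture())
  err <- expect_error(store_search(store, "Condition?onset-age=gt5"),
                      class = "fq_unsupported_search")
  expect_match(conditionMessage(err), "onset-age")
  expect_error(store_search(store, "MedicationRequest?code=x"),
               class = "fq_unsupported_search")
  expect_error(store_search(store, "Condition?recorded-date=gt2021-01-01"),
               class = "fq_unsupported_search")
})

test_that("patient_ids extracts subjects with set semantics", {
  store <- read_store(ndjson_fixture())
  obs <- store_search(store, sprintf("Observation?code=%s|2160-0", LOINC))
  expect_setequal(patient_ids(obs), c("p1", "p3"))
  pats <- store_search(store, "Patient?gender=female")
  expect_setequal(patient_ids(pats), c("p1", "p2"))
  # dedup: several resources of one patient collapse to one id
  set.seed(19)
  store2 <- random_store(n_patients = 5)
  conds <- store_search(store2, sprintf("Condition?code=%s|A01", ICD))
  manual <- unique(store2$Condition$subject[store2$Condition$code == "A01"])
  expect_setequal(patient_ids(conds), manual)
})

test_that("write/read round-trips resource counts and ids", {
  set.seed(23)
  store <- random_store()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "out.ndjson")
  write_store(store, path)
  back <- read_store(path)
  expect_equal(store_census(back), store_census(store))
  for (type in c("Patient", "Condition", "Procedure", "Observation"))
    expect_setequal(back[[type]]$id, store[[type]]$id)
  # deterministic: writing again is byte-identical
  path2 <- file.path(dir, "out2.ndjson")
  write_store(store, path2)
  expect_identical(readLines(path), readLines(path2))
})
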
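test_that("profiles validate their scaled counts", {
  expect_error(dataset_profile("small", scale = 1/7),
               class = "fq_validation_error")   # non-integer cohorts
  expect_error(dataset_profile("bg-small", scale = 1/1000),
               class = "fq_validation_error")   # non-integer background
  expect_error(dataset_profile("custom"), class = "fq_validation_error")
  expect_error(dataset_profile("small", scale = 0),
               class = "fq_validation_error")
  p <- dataset_profile("small", scale = 1/1000)
  expect_equal(p$cohortSizes, c(1000, 10000, 100000))
})

test_that("the downscaled small profile realizes the expected counts", {
  ds <- generate_dataset(dataset_profile("small", scale = 1/1000), seed = 2)
  census <- store_census(ds$store)
  expect_equal(unname(census["Patient"]), 111)
  expect_equal(unname(census["Total"]), 444)
})

test_that("every member of a cohort satisfies all four criteria and nobody else does", {
  profile <- dataset_profile("small", scale = 1/100)
  ds <- generate_dataset(profile, seed = 3)
  qs <- benchmark_queries(profile)
  sizes <- c(`1000` = 10, `10000` = 100, `100000` = 1000)
  for (lab in names(sizes)) {
    r1 <- count_query(qs[[paste0(lab, "-1")]], ds$store, ds$tree, ds$mapping)
    expect_equal(r1$patientCount, unname(sizes[lab]))
    expect_equal(r1$resourcesProcessed, unname(sizes[lab]))
    rall <- count_query(qs[[paste0(lab, "-all")]], ds$store, ds$tree, ds$mapping)
    expect_equal(rall$patientCount, unname(sizes[lab]))
    expect_equal(rall$resourcesProcessed, unname(4 * sizes[lab]))
  }
  r0 <- count_query(qs[["0"]], ds$store, ds$tree, ds$mapping)
  expect_equal(r0$patientCount, 0)
  expect_equal(r0$resourcesProcessed, 0)
  expect_length(qs, 7)   # 3 cohorts x 2 + the no-match query
})

test_that("the 100k cohort carries the published example criterion combination", {
  ct <- generate_dataset(dataset_profile("small", scale = 1/1000), seed = 1)$cohorts
  row <- ct[ct$size == 100000, ]
  expect_equal(row$gender, "female")
  expect_equal(row$conditionCode, "C50.1")
  expect_equal(row$procedureCode, "5-787")
  expect_equal(row$observationCode, "55782-7")
})

test_that("background resources spread evenly over codes, disjoint from cohort codes", {
  bg <- background_spec(conditions = 1000, conditionCodes = 30,
                        procedures = 500, procedureCodes = 7,
                        observations = 2000, observationCodes = 13)
  out <- generate_background(bg, sprintf("p-%03d", 1:50), seed = 4)
  expect_equal(nrow(out$conditions), 1000)
  expect_equal(nrow(out$procedures), 500)
  expect_equal(nrow(out$observations), 2000)
  counts <- table(out$conditions$code)
  expect_length(counts, 30)
  expect_lte(max(counts) - min(counts), 1)   # as equal as possible
  # round-robin patient attachment
  expect_lte(max(table(out$conditions$subject)) -
               min(table(out$conditions$subject)), 1)
  # disjoint from every benchmark criterion code
  ct <- generate_dataset(dataset_profile("small", scale = 1/1000),
                         seed = 1)$cohorts
  cohort_codes <- c(ct$conditionCode, ct$procedureCode, ct$observationCode)
  expect_length(intersect(unique(out$conditions$code), cohort_codes), 0)
  expect_length(intersect(unique(out$observations$code), cohort_codes), 0)
})

test_that("planted queries stay exact in the presence of background data", {
  profile <- dataset_profile("custom", cohortSizes = c(20, 50),
                             background = background_spec(
                               conditions = 300, conditionCodes = 11,
                               procedures = 200, procedureCodes = 5,
                               observations = 400, observationCodes = 3))
  ds <- generate_dataset(profile, seed = 6)
  qs <- benchmark_queries(profile)
  r <- count_query(qs[["20-all"]], ds$store, ds$tree, ds$mapping)
  expect_equal(r$patientCount, 20)
  expect_equal(r$resourcesProcessed, 80)
  r2 <- count_query(qs[["50-1"]], ds$store, ds$tree, ds$mapping)
  expect_equal(r2$patientCount, 50)
  expect_equal(r2$resourcesProcessed, 50)
})

test_that("generation is deterministic: same seed gives byte-identical NDJSON", {
  profile <- dataset_profile("custom", cohortSizes = c(10, 20),
                             background = background_spec(
                               conditions = 100, conditionCodes = 9,
                               procedures = 50, procedureCodes = 4,
                               observations = 120, observationCodes = 6))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(profile, seed = 11), d1)
  write_dataset(generate_dataset(profile, seed = 11), d2)
  for (f in c("resources.ndjson", "term-tree.json", "mapping.json",
              "manifest.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # a different seed moves the background dates/values
  d3 <- withr::local_tempdir()
  write_dataset(generate_dataset(profile, seed = 12), d3)
  expect_false(identical(readLines(file.path(d1, "resources.ndjson")),
                         readLines(file.path(d3, "resources.ndjson"))))
})

test_that("more than four cohorts switch the patient criterion to birth-year ranges", {
  profile <- dataset_profile("custom", cohortSizes = c(5, 6, 7, 8, 9))
  ds <- generate_dataset(profile, seed = 13)
  expect_true(all(ds$cohorts$patientCriterion == "birthdate"))
  qs <- benchmark_queries(profile)
  for (n in c(5, 9)) {
    r <- count_query(qs[[sprintf("%d-all", n)]], ds$store, ds$tree, ds$mapping)
    expect_equal(r$patientCount, n)
    expect_equal(r$resourcesProcessed, 4 * n)
  }
})

test_that("written data sets reload into an equivalent store with usable files", {
  profile <- dataset_profile("custom", cohortSizes = c(15))
  ds <- generate_dataset(profile, seed = 14)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  store <- read_store(file.path(dir, "resources.ndjson"))
  tree <- read_term_tree(file.path(dir, "term-tree.json"))
  mapping <- read_mapping_table(file.path(dir, "mapping.json"))
  expect_equal(store_census(store), store_census(ds$store))
  q <- benchmark_queries(profile)[["15-1"]]
  expect_equal(count_query(q, store, tree, mapping)$patientCount, 15)
})
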
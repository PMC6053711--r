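test_that("packaged fixtures match their catalogue facts", {
  fx <- packaged_fixtures()
  expect_setequal(names(fx), c("blood_sugar_kb", "blood_sugar_bundle",
                               "cbc_test", "icd10_catalogue"))
  expect_true(all(file.exists(fx)))

  cbc <- read_test_definition(fx[["cbc_test"]])
  expect_length(cbc$components, 22)
  expect_false(any(duplicated(
    vapply(cbc$components, function(c) c$code, character(1))
  )))

  catalogue <- read_artefact_catalogue(fx[["icd10_catalogue"]])
  codes <- sort(unique(unlist(lapply(catalogue, function(a) a$icd10_codes))))
  expect_identical(codes, sort(c("N30", "N04", "N39", "N10", "K75", "K72",
                                 "K71", "K81", "K85", "E05", "E03", "D50",
                                 "D72", "N41")))
  expect_length(catalogue, 14)
  # hepatitis-adjacent artefacts are tagged for in-person communication
  expect_true(catalogue[["icd_K75"]]$sensitive)
  expect_true("HEPATITIS" %in% catalogue[["icd_K75"]]$categories)

  kb <- load_knowledge_base(fx[["blood_sugar_kb"]])
  expect_identical(validation_errors(validate_knowledge_base(kb)), 0L)

  # fixture texts stay descriptive: no prescriptive assertions
  for (a in c(kb$artefacts, catalogue)) {
    expect_false(grepl("you have|your diagnosis is|must take",
                       tolower(a$text)))
  }
})

test_that("bundle generation is a pure function of config and seed", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  g1 <- generate_bundles(kb, generator_config(seed = 1, n = 10))
  g2 <- generate_bundles(kb, generator_config(seed = 1, n = 10))
  expect_identical(g1, g2)
  g3 <- generate_bundles(kb, generator_config(seed = 2, n = 10))
  expect_false(identical(g1$bundles, g3$bundles))

  # generated bundles always survive the intake syntax check
  for (b in g1$bundles) {
    json <- jsonlite::toJSON(labdss:::bundle_to_list(b), auto_unbox = TRUE,
                             digits = NA)
    expect_s3_class(parse_order_bundle(json), "lab_order_bundle")
  }
})

test_that("abnormal_fraction bounds where values land", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  in_interval <- function(kb, bundle) {
    ok <- TRUE
    for (cmp in kb$tests[["blood_sugar"]]$components) {
      v <- resolve_value(bundle, cmp$code, cmp$unit)
      if (v < cmp$reference_low || v > cmp$reference_high) ok <- FALSE
    }
    ok
  }
  normal <- generate_bundles(kb, generator_config(seed = 5, n = 20,
                                                  abnormal_fraction = 0))
  expect_true(all(vapply(normal$bundles, in_interval, logical(1), kb = kb)))
  # the fixture rules trigger only on out-of-interval values, so nothing fires
  expect_true(all(lengths(normal$expected_rules) == 0))
  for (b in normal$bundles[1:5]) {
    expect_length(run_inference(kb, b)$artefacts, 0)
  }

  abnormal <- generate_bundles(kb, generator_config(seed = 5, n = 20,
                                                    abnormal_fraction = 1))
  expect_false(any(vapply(abnormal$bundles, in_interval, logical(1),
                          kb = kb)))
})

test_that("generator ground truth agrees with the engine end-to-end", {
  kb <- load_knowledge_base(fixture_paths[["blood_sugar_kb"]])
  for (frac in c(0.5, 1)) {
    gen <- generate_bundles(kb, generator_config(seed = 17, n = 50,
                                                 abnormal_fraction = frac))
    for (i in seq_along(gen$bundles)) {
      fired <- emitted_rule_ids(run_inference(kb, gen$bundles[[i]]))
      expect_identical(sort(fired), sort(gen$expected_rules[[i]]),
                       info = sprintf("fraction %g bundle %d", frac, i))
    }
  }
})

test_that("components without a reference interval use the default band and are flagged", {
  kb <- mini_kb()  # component c has no interval
  kb$rules[["r3"]] <- NULL  # drop draft rule referencing c via EQ
  kb$configurations[["panel"]]$direct_rule_ids <- c("r1", "r2")
  gen <- generate_bundles(kb, generator_config(seed = 2, n = 5))
  expect_true("c" %in% gen$unbounded_components)
  for (b in gen$bundles) {
    v <- resolve_value(b, "c", "g/L")
    expect_true(v >= 0 && v <= 100)
  }
})

test_that("rater-label generation hits its rates in expectation", {
  # no disagreement -> identical raters, kappa undefined or 1
  labels <- generate_rater_labels(200, error_rate = 0.1,
                                  disagreement_rate = 0, seed = 3)
  expect_identical(labels$rater_a, labels$rater_b)
  expect_equal(cohens_kappa(labels$rater_a, labels$rater_b)$kappa, 1)

  # zero error rate -> all consensus labels CORRECT
  clean <- generate_rater_labels(100, 0, 0.05, seed = 4)
  expect_true(all(clean$consensus == "CORRECT"))

  # mistake counts concentrate around n * error_rate across seeds
  counts <- vapply(1:40, function(s) {
    sum(generate_rater_labels(1000, 0.007, 0, seed = s)$consensus ==
          "INCORRECT")
  }, numeric(1))
  expect_equal(mean(counts), 7, tolerance = 0.35)
  expect_true(all(counts <= 25))
})

test_that("survey generation is seeded and tracks target means", {
  means <- c(BI1 = 5.7, BI2 = 6.1, IM1 = 6.2)
  s1 <- generate_survey(120, means, seed = 8)
  s2 <- generate_survey(120, means, seed = 8)
  expect_identical(s1, s2)
  expect_true(all(as.matrix(s1[names(means)]) %in% 1:7))

  # boundary target -> constant column
  expect_true(all(generate_survey(50, c(PU1 = 7), seed = 1)$PU1 == 7))

  # Monte-Carlo: realised item means stay within sampling error of targets
  devs <- vapply(1:200, function(s) {
    got <- generate_survey(120, means, seed = s)
    mean(abs(vapply(names(means), function(i) mean(got[[i]]), numeric(1)) -
               means))
  }, numeric(1))
  expect_lt(mean(devs), 0.2)

  expect_error(generate_survey(10, c(BI1 = 8), seed = 1),
               class = "labdss_domain_error")
})
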
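test_that("classification metrics follow the printed definitions", {
  m <- classification_metrics(1000, 7, tp = 993, fn = 7)
  expect_equal(m$error_rate, 0.007)
  expect_equal(m$accuracy, 0.993)
  expect_equal(m$precision, 0.993)
  expect_equal(round(m$precision, 2), 0.99)
  expect_equal(m$error_rate + m$accuracy, 1)

  perfect <- classification_metrics(50, 0, tp = 50, fn = 0)
  expect_equal(perfect$error_rate, 0)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_measure, 1)

  expect_equal(f_measure(0.5, 1.0), 2 / 3)
  expect_true(is.na(f_measure(0, 0)))
  expect_true(is.na(classification_metrics(10, 1)$recall))
  expect_error(classification_metrics(10, 11),
               class = "labdss_domain_error")
})

test_that("F-measure lies between precision and recall", {
  set.seed(21)
  for (i in 1:200) {
    p <- runif(1)
    r <- runif(1)
    f <- f_measure(p, r)
    if (is.na(f)) next
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("Cohen's kappa matches hand-computed contingency tables", {
  # perfect agreement
  x <- rep(c("CORRECT", "INCORRECT"), c(8, 2))
  expect_equal(cohens_kappa(x, x)$kappa, 1)

  # 2x2 table a=45, b=5, c=5, d=45: po 0.9, pe 0.5, kappa 0.8
  a <- rep(c("P", "P", "N", "N"), c(45, 5, 5, 45))
  b <- rep(c("P", "N", "P", "N"), c(45, 5, 5, 45))
  k <- cohens_kappa(a, b)
  expect_equal(k$observed_agreement, 0.9)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.8)

  # constant rater vs 50/50 rater: po 0.5, pe 0.5, kappa 0
  a <- rep(c("P", "N"), each = 50)
  b <- rep("P", 100)
  k <- cohens_kappa(a, b)
  expect_equal(k$observed_agreement, 0.5)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0)

  # degenerate: both raters constant on the same label
  expect_equal(cohens_kappa(rep("P", 5), rep("P", 5))$kappa, 1)
  expect_true(is.na(cohens_kappa(c("P", "P"), c("P", "N"))$kappa) ||
                cohens_kappa(c("P", "P"), c("P", "N"))$kappa < 1)

  expect_error(cohens_kappa(c("a", "b"), "a"),
               class = "labdss_domain_error")
})

test_that("kappa is symmetric and matches the brute-force oracle", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    cats <- sample(c("CORRECT", "INCORRECT", "UNSURE"),
                   sample(2:3, 1))
    a <- sample(cats, n, replace = TRUE)
    b <- sample(cats, n, replace = TRUE)
    k_ab <- cohens_kappa(a, b)
    if (k_ab$expected_agreement < 1) {
      expect_equal(k_ab$kappa, oracle_kappa(a, b), tolerance = 1e-12)
    }
    expect_equal(k_ab$kappa, cohens_kappa(b, a)$kappa, tolerance = 1e-12)
  }
})

test_that("acceptance scoring aggregates items into criterion means", {
  # constant responses give constant statistics
  map <- acceptance_item_map()
  const <- as.data.frame(stats::setNames(
    rep(list(rep(4L, 6)), nrow(map)), map$item
  ))
  s <- score_acceptance(const, map)
  expect_true(all(s$items$mean == 4))
  expect_true(all(s$items$median == 4))
  expect_true(all(s$criteria$mean == 4))

  # out-of-range values are rejected naming respondent and item
  bad <- const
  bad$IM2[3] <- 9L
  err <- tryCatch(score_acceptance(bad, map),
                  labdss_domain_error = function(e) e)
  expect_match(conditionMessage(err), "respondent 3")
  expect_match(conditionMessage(err), "IM2")

  # criterion means are invariant to respondent ordering
  set.seed(44)
  resp <- generate_survey(30, stats::setNames(runif(11, 3, 7), map$item),
                          seed = 7)[map$item]
  s1 <- score_acceptance(resp, map)
  s2 <- score_acceptance(resp[sample(nrow(resp)), , drop = FALSE], map)
  expect_equal(s1$criteria, s2$criteria)

  # an added all-k respondent pulls every item mean toward k
  with_seven <- rbind(resp, stats::setNames(as.list(rep(7L, 11)), map$item))
  s3 <- score_acceptance(with_seven, map)
  expect_true(all(s3$items$mean >= s1$items$mean - 1e-12))

  # the item map must assign 2 + 3 + 3 + 3 items
  short_map <- map[-1, ]
  expect_error(score_acceptance(const, short_map),
               class = "labdss_domain_error")
})

test_that("age subgroups are scored separately", {
  map <- acceptance_item_map()
  resp <- generate_survey(40, stats::setNames(rep(5.5, 11), map$item),
                          seed = 11)[map$item]
  age <- c(rep(70, 10), rep(40, 30))
  s <- score_acceptance(resp, map, age = age)
  expect_named(s$subgroups, c("over_60", "under_60"))
  expect_identical(s$subgroups$over_60$n, 10L)
  expect_identical(s$subgroups$under_60$n, 30L)
  expect_equal(
    s$subgroups$under_60$items$mean[1],
    mean(resp[["BI1"]][age < 60])
  )
})

test_that("proportion converts count ratios to percentages", {
  expect_equal(proportion(120, 500), 24)
  expect_equal(proportion(0, 7), 0)
  expect_equal(proportion(7, 7), 100)
  expect_error(proportion(1, 0), class = "labdss_domain_error")
  expect_error(proportion(8, 7), class = "labdss_domain_error")
})
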
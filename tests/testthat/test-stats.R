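test_that("the pooled t-test matches hand-computed values", {
  ht <- ttest_independent(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ht$t, -3.674235, tolerance = 1e-6)
  expect_equal(ht$df, 4)
  expect_equal(ht$p, 0.02131164, tolerance = 1e-6)
  # Swapping groups negates t and keeps p.
  sw <- ttest_independent(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -ht$t)
  expect_equal(sw$p, ht$p)
  # Identical groups.
  id <- ttest_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
})

test_that("summary-statistics and raw-data forms agree exactly", {
  set.seed(10)
  for (i in 1:10) {
    a <- rnorm(sample(3:9, 1), 10, 2)
    b <- rnorm(sample(3:9, 1), 11, 3)
    raw <- ttest_independent(a, b)
    smry <- ttest_independent_summary(mean(a), sd(a), length(a),
                                      mean(b), sd(b), length(b))
    expect_equal(smry$t, raw$t, tolerance = 1e-12)
    expect_equal(smry$df, raw$df)
    expect_equal(smry$p, raw$p, tolerance = 1e-12)
    raw_w <- ttest_independent(a, b, welch = TRUE)
    smry_w <- ttest_independent_summary(mean(a), sd(a), length(a),
                                        mean(b), sd(b), length(b),
                                        welch = TRUE)
    expect_equal(smry_w$t, raw_w$t, tolerance = 1e-12)
    expect_equal(smry_w$df, raw_w$df, tolerance = 1e-10)
  }
})

test_that("degenerate variance cases follow the stated convention", {
  expect_equal(ttest_independent_summary(5, 0, 6, 5, 0, 6)$p, 1)
  expect_error(ttest_independent_summary(5, 0, 6, 6, 0, 6), "infinite")
  expect_equal(ttest_paired(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(ttest_paired(c(1, 2, 3), c(2, 3, 4)), "infinite")
})

test_that("the paired test is the one-sample t on differences", {
  set.seed(4)
  a <- rnorm(8, 5, 1)
  b <- a + rnorm(8, 0.5, 0.7)
  got <- ttest_paired(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$df, 7)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 7), tolerance = 1e-12)
})

test_that("cohort comparison flags diastolic but not systolic differences", {
  res <- run_cohort_experiment(cohort_spec_zl(seed = 21),
                               cohort_spec_zdf(seed = 22))
  cmp <- res$comparison
  expect_setequal(
    cmp$parameter, c("ef", "pfr", "third_mfr", "tpfr_ms", "hr", "edv", "esv"))
  # Identical cohorts: everything non-significant.
  same <- compare_cohorts(res$results_a, res$results_a)
  expect_true(all(!same$significant))
  expect_true(all(same$p == 1))
  expect_error(compare_cohorts(res$results_a[1, ], res$results_b), "2 subjects")
})

test_that("the diastolic deficit is detected in most simulated studies", {
  hits <- sapply(1:8, function(s) {
    cmp <- run_cohort_experiment(cohort_spec_zl(seed = 100 + s),
                                 cohort_spec_zdf(seed = 200 + s))$comparison
    c(pfr = cmp$p[cmp$parameter == "pfr"] < 0.05,
      third = cmp$p[cmp$parameter == "third_mfr"] < 0.05,
      ef = cmp$p[cmp$parameter == "ef"] < 0.05,
      hr = cmp$p[cmp$parameter == "hr"] < 0.05)
  })
  expect_gte(sum(hits["pfr", ]), 5)    # power ~0.9 at alpha 0.05
  expect_gte(sum(hits["third", ]), 4)
  expect_lte(sum(hits["ef", ]), 5)     # power ~0.2: mostly n.s.
  expect_lte(sum(hits["hr", ]), 5)
})
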
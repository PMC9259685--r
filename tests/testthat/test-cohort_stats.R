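cohort_counts <- function() {
  read.table(system.file("extdata", "gba_cohort_counts.tsv",
                         package = "paralogcnv"),
             header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

test_that("carrier exclusion leaves the published denominators", {
  counts <- cohort_counts()
  pd <- expand_cohort_counts(counts[counts$cohort == "PD", ])
  expect_equal(nrow(pd), 2325L + 1255L)
  ex <- exclude_carriers(pd, "n409s")
  expect_equal(sum(ex$arm == "case"), 2197L)
  expect_equal(sum(ex$arm == "control"), 1097L)
  expect_equal(as.integer(attr(ex, "n_removed")["case"]), 128L)

  ## excluding an all-carrier class empties the table with a warning
  allc <- pd
  allc$n409s <- TRUE
  expect_warning(e2 <- exclude_carriers(allc, "n409s"), "empty")
  expect_equal(nrow(e2), 0L)
  ## excluding an absent class is the identity
  none <- pd
  none$n409s <- FALSE
  expect_equal(nrow(exclude_carriers(none, "n409s")), nrow(pd))
})

test_that("odds ratios reproduce the published cohort comparisons", {
  expect_equal(round(odds_ratio_counts(171, 2026, 43, 1054)$or_value, 2),
               2.07)
  expect_equal(round(odds_ratio_counts(298, 2241, 67, 1855)$or_value, 2),
               3.68)
  ## PD severe: printed as 2.12; the cross-product of the published counts
  ## is 2.1277 (agreement to one unit in the last printed digit)
  expect_lt(abs(odds_ratio_counts(38, 2159, 9, 1088)$or_value - 2.12),
            0.011)

  or1 <- odds_ratio_counts(50, 50, 50, 50)
  expect_equal(or1$or_value, 1)
  expect_true(or1$ci_low <= 1 && 1 <= or1$ci_high)

  orz <- odds_ratio_counts(0, 100, 10, 90)
  expect_true(orz$corrected)
  expect_gt(orz$or_value, 0)
  expect_error(odds_ratio_counts(0, 0, 5, 5), "margin")
})

test_that("odds ratio equals the logistic-regression MLE", {
  set.seed(19)
  for (i in 1:100) {
    cells <- sample(1:500, 4, replace = TRUE)
    or <- odds_ratio_counts(cells[1], cells[2], cells[3], cells[4])
    fit <- glm(cbind(c(cells[1], cells[3]), c(cells[2], cells[4])) ~
                 c(1, 0), family = binomial)
    expect_equal(or$or_value, unname(exp(coef(fit)[2])),
                 tolerance = 1e-6)
  }
})

test_that("prevalences print at the published precision", {
  expect_equal(prevalence_counts(171, 2197), 7.8)
  expect_equal(prevalence_counts(43, 1097), 3.9)
  expect_equal(prevalence_counts(298, 2539), 11.7)
  expect_equal(prevalence_counts(67, 1922), 3.5)
  expect_equal(prevalence_counts(38, 2197), 1.7)
  ## 9/1097 = 0.82%; the published table prints 0.8 (1 d.p.)
  expect_equal(round(prevalence_counts(9, 1097), 1), 0.8)
  expect_equal(prevalence_counts(7, 146), 4.8)
  expect_equal(prevalence_counts(71, 10407), 0.68)  # 2 d.p. below 1%
  expect_equal(prevalence_counts(0, 50), 0)
  expect_error(prevalence_counts(0, 0), "empty")

  ## carrier + non-carrier proportions always total 100
  tab <- expand_cohort_counts(cohort_counts()[2:3, ])
  p <- 100 * mean(tab$any_variant[tab$arm == "case"])
  q <- 100 * mean(!tab$any_variant[tab$arm == "case"])
  expect_equal(p + q, 100)
})

test_that("proportion tests agree with exact hypergeometric enumeration", {
  expect_equal(proportion_test(10, 100, 10, 100), 1.0)

  ## oracle: full enumeration of the hypergeometric tail probabilities
  a <- 7; n1 <- 146; b <- 71; n2 <- 10407
  k <- a + b; N <- n1 + n2
  probs <- dhyper(0:k, n1, n2, k)
  p_exact <- sum(probs[probs <= dhyper(a, n1, n2, k) * (1 + 1e-7)])
  got <- proportion_test(a, n1, b, n2)
  expect_equal(got, p_exact, tolerance = 1e-10)
  ## the published comparison point for these counts is 9.77e-5
  expect_lt(got, 1e-3)

  expect_lt(proportion_test(0, 50, 30, 1000), 1)
  expect_gt(proportion_test(0, 50, 30, 1000), 0)
  expect_equal(round(proportion_test(30, 100, 20, 100, "chisq"), 3),
               round(chisq.test(matrix(c(30, 70, 20, 80), 2,
                                       byrow = TRUE))$p.value, 3))
})
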
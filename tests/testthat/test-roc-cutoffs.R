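test_that("ROC endpoints, separation and orientation behave", {
  v <- c(0.30, 0.35, 0.45, 0.50)
  lab <- c(0, 0, 1, 1)
  r <- rocCurve(v, lab)
  expect_equal(auc(r), 1)
  expect_equal(r@curve$fpr[1], 0); expect_equal(r@curve$tpr[1], 0)
  expect_equal(utils::tail(r@curve$fpr, 1), 1)
  expect_equal(utils::tail(r@curve$tpr, 1), 1)

  # flipped orientation on tie-free data is the complement
  expect_equal(auc(rocCurve(v, lab, direction = "<")), 0)
  expect_error(rocCurve(v, rep(1, 4)), "single-class")
})

test_that("AUC equals Mann-Whitney U/(n1*n2) against the pairwise oracle", {
  set.seed(71)
  for (i in 1:100) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    vals <- c(sample(1:10, n1, TRUE), sample(3:12, n2, TRUE)) +
      ifelse(runif(n1 + n2) < 0.5, 0, 0.5)   # plenty of ties
    lab <- rep(c(0, 1), c(n1, n2))
    a <- auc(rocCurve(vals, lab))
    expect_equal(a, pairwiseAUC(vals, lab), tolerance = 1e-12)
    expect_equal(a, mannWhitney(vals[lab == 1], vals[lab == 0])$U /
                   (n1 * n2), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms and complements", {
  set.seed(81)
  v <- rnorm(40); lab <- rep(c(0, 1), 20)
  a <- auc(rocCurve(v, lab))
  expect_equal(auc(rocCurve(exp(v), lab)), a, tolerance = 1e-12)
  expect_equal(auc(rocCurve(qnorm(pnorm(v))^3 + 5 * v, lab)), a,
               tolerance = 1e-12)
  expect_equal(auc(rocCurve(-v, lab)), 1 - a, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on random data", {
  set.seed(91)
  v <- c(rnorm(30, 0.35, 0.06), rnorm(25, 0.43, 0.09))
  lab <- rep(c(0, 1), c(30, 25))
  a <- auc(rocCurve(v, lab))
  pr <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                       direction = "<")))
  expect_equal(a, pr, tolerance = 1e-12)
  dl <- delongCI(v, lab)
  ci <- as.numeric(pROC::ci.auc(pROC::roc(lab, v, quiet = TRUE,
                                          direction = "<"),
                                method = "delong"))
  expect_equal(c(dl$ciLow, dl$auc, dl$ciHigh), ci, tolerance = 1e-6)
})

test_that("binormal sampling converges to the closed-form AUC", {
  set.seed(101)
  n <- 20000
  v <- c(rnorm(n, 0, 1), rnorm(n, 1, 1.5))
  a <- auc(rocCurve(v, rep(c(0, 1), each = n)))
  expect_equal(a, pnorm(1 / sqrt(1 + 1.5^2)), tolerance = 0.01)
})

test_that("hybrid interval brackets the estimate and narrows with n", {
  for (x in c(0, 1, 2, 5, 9, 10)) {
    ci <- wilsonCI(x, 10)
    expect_lte(ci[["lo"]], 100 * x / 10 + 1e-12)
    expect_gte(ci[["hi"]], 100 * x / 10 - 1e-12)
  }
  expect_equal(wilsonCI(0, 10)[["lo"]], 0)
  expect_equal(wilsonCI(10, 10)[["hi"]], 100)
  w1 <- wilsonCI(30, 100, method = "wilson")
  w2 <- wilsonCI(300, 1000, method = "wilson")
  expect_lt(w2[["hi"]] - w2[["lo"]], w1[["hi"]] - w1[["lo"]])
})

test_that("plain Wilson matches prop.test's score interval", {
  for (cc in list(c(30, 33), c(21, 30), c(7, 19))) {
    w <- wilsonCI(cc[1], cc[2], method = "wilson") / 100
    pt <- prop.test(cc[1], cc[2], correct = FALSE)$conf.int
    expect_equal(unname(w), as.numeric(pt), tolerance = 1e-10)
  }
})

test_that("cutoff table uses the strict > rule with exact count fractions", {
  vals <- c(0.30, 0.35, 0.45, 0.50)
  lab <- c(0, 0, 1, 1)
  tab <- cutoffTable(vals, lab, thresholds = 0.40)
  expect_equal(tab$sensitivity, 100)
  expect_equal(tab$specificity, 100)
  expect_true(is.infinite(tab$likelihoodRatio))

  # threshold outside the data range still yields a (degenerate) row
  out <- cutoffTable(vals, lab, thresholds = 0.9)
  expect_equal(out$sensitivity, 0)
  expect_equal(out$specificity, 100)

  # auto thresholds are midpoints of consecutive distinct values
  auto <- cutoffTable(vals, lab)
  expect_equal(auto$threshold, c(0.325, 0.40, 0.475))

  # a value exactly at the threshold is classified negative (strict >)
  tb <- cutoffTable(c(0.4, 0.5), c(0, 1), thresholds = 0.4)
  expect_equal(tb$tn, 1)
  expect_equal(tb$tp, 1)
})

test_that("likelihood ratios come from exact fractions", {
  expect_equal(likelihoodRatio(0.5, 0.5), 1)
  expect_equal(likelihoodRatio(23 / 30, 25 / 33), 3.163, tolerance = 5e-4)
  expect_equal(likelihoodRatio(11 / 15, 34 / 35), 25.67, tolerance = 5e-3)
  expect_true(is.infinite(likelihoodRatio(0.8, 1)))
  # rounding percentages first would give 25.64, not the printed 25.67
  expect_false(isTRUE(all.equal(round(73.33 / (100 - 97.14), 2), 25.67)))
})

test_that("Youden row maximizes sensitivity + specificity", {
  set.seed(111)
  v <- c(rnorm(30, 0.34, 0.06), rnorm(30, 0.44, 0.09))
  lab <- rep(c(0, 1), each = 30)
  tab <- cutoffTable(v, lab)
  yr <- youdenRow(tab)
  expect_equal(yr$sensitivity + yr$specificity,
               max(tab$sensitivity + tab$specificity))
})
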
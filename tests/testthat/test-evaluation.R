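# Agreement statistics: contingency tables, Cohen's kappa, rank-sum
# ROC/AUC and the composition report.

test_that("contingency tables cross-tabulate and are order-invariant", {
  t1 <- buildContingency(c("low"), c("low"))
  expect_equal(unname(tableCounts(t1)), matrix(c(1L, 0L, 0L, 0L), 2, 2))
  t2 <- buildContingency(rep("high", 5), rep("high", 5))
  expect_equal(tableCounts(t2)[2, 2], 5L)
  set.seed(61)
  v <- sample(c("low", "high"), 40, replace = TRUE)
  d <- sample(c("low", "high"), 40, replace = TRUE)
  p <- sample(40)
  expect_equal(tableCounts(buildContingency(v, d)),
               tableCounts(buildContingency(v[p], d[p])))
  # prefixed labels are accepted
  expect_equal(tableCounts(buildContingency(c("vTSR-low", "vTSR-high"),
                                            c("dTSR-low", "dTSR-high"))),
               tableCounts(buildContingency(c("low", "high"),
                                            c("low", "high"))))
  expect_error(buildContingency(c("low"), c("low", "high")), "length")
  expect_error(buildContingency(c("low"), c("medium")), "low/high")
})

test_that("kappa hits its closed-form anchors", {
  perfect <- new("ContingencyTable2x2",
                 counts = matrix(c(50L, 0L, 0L, 50L), 2, 2))
  expect_equal(cohenKappa(perfect), 1)
  indep <- new("ContingencyTable2x2",
               counts = matrix(c(25L, 25L, 25L, 25L), 2, 2))
  expect_equal(cohenKappa(indep), 0)
  # the study's published cross-table counts
  expect_equal(round(cohenKappa(table2Counts()), 4), 0.6738)
  # simultaneous row/column label swap leaves kappa unchanged
  m <- tableCounts(table2Counts())
  swapped <- new("ContingencyTable2x2", counts = m[2:1, 2:1])
  expect_equal(cohenKappa(swapped), cohenKappa(table2Counts()))
  expect_lte(cohenKappa(table2Counts()), 1)
  # degenerate single-cell table
  onecell <- new("ContingencyTable2x2",
                 counts = matrix(c(9L, 0L, 0L, 0L), 2, 2))
  expect_warning(k <- cohenKappa(onecell), "undefined")
  expect_true(is.na(k))
})

test_that("AUC anchors: separation, pure ties, complement symmetry", {
  expect_equal(rocAuc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(5, 8), c(0, 1, 0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(62)
  s <- runif(25); t <- rbinom(25, 1, 0.5)
  if (length(unique(t)) == 2)
    expect_equal(rocAuc(s, t)$auc + rocAuc(-s, t)$auc, 1)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "both classes")
  # low/high labels are accepted with high as the positive class
  expect_equal(rocAuc(c(10, 90), c("low", "high"))$auc, 1)
})

test_that("rank-sum AUC equals exhaustive pair counting", {
  set.seed(63)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    s <- sample(seq(0, 100, by = 5), n, replace = TRUE)  # force ties
    t <- rbinom(n, 1, 0.5)
    if (length(unique(t)) < 2) next
    expect_equal(rocAuc(s, t)$auc, bruteAuc(s, t))
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  s <- runif(40, 0, 100); t <- rbinom(40, 1, 0.6)
  expect_equal(rocAuc(s, t)$auc,
               as.numeric(pROC::auc(pROC::roc(t, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("the agreement report reproduces the published composition", {
  rep <- agreementReport(table2Counts())
  expect_equal(unname(rep$dtsr_marginal_pct), c(33.80, 66.20))
  expect_equal(unname(rep$vtsr_marginal_pct), c(35.75, 64.25))
  expect_equal(unname(rep$within_dtsr_pct[1, 1]), 80.99)  # vTSR-low | dTSR-low
  expect_equal(unname(rep$within_dtsr_pct[2, 2]), 87.34)  # vTSR-high | dTSR-high
  expect_equal(unname(colSums(rep$within_dtsr_pct)), c(100, 100),
               tolerance = 0.011)
  expect_equal(rep$p_o, 305 / 358)
  # degenerate n = 1
  one <- new("ContingencyTable2x2",
             counts = matrix(c(1L, 0L, 0L, 0L), 2, 2))
  suppressWarnings(r1 <- agreementReport(one))
  expect_equal(unname(r1$dtsr_marginal_pct), c(100, 0))
})

test_that("the ROC curve is monotone and ends at (1, 1)", {
  set.seed(65)
  s <- runif(30, 0, 100); t <- rbinom(30, 1, 0.5)
  if (length(unique(t)) < 2) t[1:2] <- c(0, 1)
  rc <- rocAuc(s, t)$curve
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_equal(rc$sensitivity[nrow(rc)], 1)
  expect_equal(rc$fpr[nrow(rc)], 1)
})
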
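test_that("threshold metrics match hand-computed confusion tables", {
  cc <- function(tp, fp, tn, fn)
    structure(list(TP = tp, FP = fp, TN = tn, FN = fn), class = "ConfusionCounts")
  expect_equal(precisionScore(cc(5, 0, 10, 0)), 1)
  expect_equal(precisionScore(cc(0, 5, 10, 0)), 0)
  expect_equal(precisionScore(cc(3, 1, 0, 0)), 0.75)
  expect_equal(balancedAccuracy(cc(3, 2, 8, 1)), 0.5 * (0.75 + 0.8))
  expect_equal(matthewsCC(cc(3, 2, 8, 1)), 22 / sqrt(1800), tolerance = 1e-12)
  ## perfect, constant and inverted predictors
  expect_equal(balancedAccuracy(cc(4, 0, 12, 0)), 1)
  expect_equal(matthewsCC(cc(4, 0, 12, 0)), 1)
  expect_equal(matthewsCC(cc(0, 12, 0, 4)), -1)
  expect_equal(balancedAccuracy(cc(0, 0, 12, 4)), 0.5)  # calls everything order
  ## undefined cases come back NA, never zero
  expect_warning(p <- precisionScore(cc(0, 0, 10, 2)), "undefined")
  expect_true(is.na(p))
  expect_warning(b <- balancedAccuracy(cc(0, 0, 10, 0)), "undefined")
  expect_true(is.na(b))
  expect_warning(m <- matthewsCC(cc(0, 0, 10, 2)), "undefined")
  expect_true(is.na(m))
})

test_that("confusion counts pool residues across sequences", {
  calls <- list(c(1, 0, 1), c(0, 0))
  truth <- list(c(1, 0, 0), c(0, 1))
  cc <- confusionCounts(calls, truth)
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")], use.names = FALSE),
               c(1L, 1L, 2L, 1L))
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 5L)
})

test_that("ROC/AUC matches pair enumeration and the rank statistic", {
  r <- rocAUC(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)    # 3 of the 4 positive-negative pairs ordered
  ## perfect separation and label-independent scores
  expect_equal(rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  set.seed(31)
  sc <- runif(4000)
  tr <- rbinom(4000, 1, 0.3)
  expect_equal(rocAUC(sc, tr)$auc, 0.5, tolerance = 0.05)
  ## agreement with the tie-corrected rank form, including heavy ties
  scoresT <- sample(seq(0, 1, by = 0.1), 300, replace = TRUE)
  truthT <- rbinom(300, 1, 0.4)
  expect_equal(rocAUC(scoresT, truthT)$auc, rankAUC(scoresT, truthT),
               tolerance = 1e-12)
  expect_warning(u <- rocAUC(c(0.2, 0.8), c(1, 1))$auc, "single class")
  expect_true(is.na(u))
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(77)
  sc <- rnorm(200)
  tr <- rbinom(200, 1, 0.25)
  base <- rocAUC(sc, tr)$auc
  expect_equal(rocAUC(exp(sc), tr)$auc, base, tolerance = 1e-12)
  expect_equal(rocAUC(2 * sc - 7, tr)$auc, base, tolerance = 1e-12)
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- round(runif(500), 2)  # rounding forces ties
  tr <- rbinom(500, 1, 0.2)
  ref <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE, direction = "<")))
  expect_equal(rocAUC(sc, tr)$auc, ref, tolerance = 1e-10)
})

test_that("the best-MCC threshold sweep is deterministic with low ties winning", {
  sc <- c(0.1, 0.3, 0.3, 0.7, 0.9)
  tr <- c(0, 0, 1, 1, 1)
  best <- bestMCCThreshold(sc, tr)
  m <- sapply(sort(unique(sc)), function(t)
    suppressWarnings(matthewsCC(confusionCounts(as.integer(sc >= t), tr))))
  expect_equal(best$mcc, max(m, na.rm = TRUE))
  ## a duplicated optimum must resolve to the smallest threshold:
  ## thresholds 0.4 and 0.9 here both reach MCC = 0.577
  sc2 <- c(0.1, 0.4, 0.6, 0.9)
  tr2 <- c(0, 1, 0, 1)
  expect_equal(bestMCCThreshold(sc2, tr2)$threshold, 0.4)
  expect_identical(bestMCCThreshold(sc2, tr2), bestMCCThreshold(sc2, tr2))
})

test_that("pooled and per-sequence evaluation modes both work", {
  scores <- list(c(0.9, 0.1, 0.8), c(0.2, 0.7))
  truth <- list(c(1, 0, 1), c(0, 1))
  pooled <- evaluatePredictions(scores, truth, threshold = 0.5)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$auc, 1)
  per <- evaluatePredictions(scores, truth, threshold = 0.5, perSequence = TRUE)
  expect_equal(nrow(per), 2L)
  expect_equal(per$auc, c(1, 1))
})
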
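mkLabels <- function(nAgg, nInd) {
  data.frame(case_id = sprintf("c%03d", seq_len(nAgg + nInd)),
             label = rep(c("aggressive", "indolent"), c(nAgg, nInd)))
}

test_that("stratified folds balance both classes to within one case", {
  f <- stratifiedFolds(mkLabels(36, 69), kFolds = 10, seed = 3)
  perFold <- table(f$label, f$fold)
  expect_true(all(perFold["aggressive", ] %in% 3:4))
  expect_true(all(perFold["indolent", ] %in% 6:7))
  # partition: every case exactly once
  expect_setequal(f$case_id, mkLabels(36, 69)$case_id)
  expect_equal(anyDuplicated(f$case_id), 0L)
  # a different seed reshuffles but keeps the balance
  f2 <- stratifiedFolds(mkLabels(36, 69), kFolds = 10, seed = 4)
  expect_false(identical(f$fold, f2$fold))
  expect_true(all(table(f2$label, f2$fold)["aggressive", ] %in% 3:4))
})

test_that("small exact and leave-one-out fold layouts work", {
  f <- stratifiedFolds(mkLabels(4, 6), kFolds = 2, seed = 1)
  tab <- table(f$label, f$fold)
  expect_true(all(tab["aggressive", ] == 2))
  expect_true(all(tab["indolent", ] == 3))

  loo <- stratifiedFolds(mkLabels(3, 5), kFolds = 8, seed = 1)
  expect_equal(sort(loo$fold), 1:8)

  expect_error(stratifiedFolds(mkLabels(4, 20), kFolds = 10, seed = 1),
               class = "wd_infeasible_stratification")
})

test_that("excluded cases are never assigned to a fold", {
  lab <- rbind(mkLabels(12, 14),
               data.frame(case_id = "x1", label = "excluded"))
  f <- stratifiedFolds(lab, kFolds = 4, seed = 2)
  expect_false("x1" %in% f$case_id)
  expect_equal(nrow(f), 26)
})

test_that("classification metrics match the confusion-matrix arithmetic", {
  p <- rep(c(1, 1, 0, 0), c(7, 3, 6, 4))
  y <- rep(c(1, 0, 0, 1), c(7, 3, 6, 4))
  m <- classificationMetrics(p, y)
  expect_equal(unname(m["accuracy"]), 0.65)
  expect_equal(unname(m["ppv"]), 0.7)
  expect_equal(unname(m["npv"]), 0.6)

  perfect <- classificationMetrics(c("aggressive", "indolent"),
                                   c("aggressive", "indolent"))
  expect_equal(as.vector(perfect), c(1, 1, 1))

  noPos <- classificationMetrics(c(0, 0), c(1, 0))
  expect_true(is.na(noPos["ppv"]))
  expect_identical(attr(noPos, "undefined"), "ppv")
})

test_that("ROC/AUC equals the pairwise Mann-Whitney computation", {
  expect_equal(rocAuc(c(0.9, 0.7, 0.4, 0.2), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(rocAuc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), class = "wd_validation_error")

  set.seed(23)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(1:2, 1))  # coarse grid to force ties
    expect_equal(rocAuc(s, y)$auc, oracleAuc(s, y), tolerance = 1e-12)
  }

  # curve endpoints and monotonicity
  r <- rocAuc(c(0.1, 0.5, 0.5, 0.9), c(0, 1, 0, 1))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(38, 1, 0.4))
    s <- round(runif(40), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation predicts each case exactly once and is perfect
          on separable data", {
  se <- normalizeBatch(simulateCohort(separableConfig(nAgg = 12, nInd = 20,
                                                      seed = 33)))
  lab <- assignLabels(se)
  cv <- runCV(se, lab, panelDirections, kFolds = 4, seed = 9)
  expect_setequal(cv@predictions$case_id, colnames(se))
  expect_equal(anyDuplicated(cv@predictions$case_id), 0L)
  expect_equal(unname(cv@metrics["accuracy"]), 1)
  expect_equal(unname(cv@metrics["ppv"]), 1)
  expect_equal(unname(cv@metrics["npv"]), 1)
  expect_equal(unname(cv@metrics["auc"]), 1)
})

test_that("out-of-fold accuracy does not beat training accuracy on average", {
  trainAcc <- cvAcc <- numeric(6)
  for (r in seq_len(6)) {
    se <- normalizeBatch(simulateCohort(cohortConfig(
      nAggressive = 30, nIndolent = 40, nBatches = 1, batchShiftSd = 0,
      batchScaleRange = c(1, 1), seed = 100 + r)))
    lab <- assignLabels(se)
    clf <- fitWD(se, lab, panelDirections)
    trainAcc[r] <- trainingAccuracy(clf, se, lab)
    cvAcc[r] <- runCV(se, lab, panelDirections, kFolds = 5,
                      seed = r)@metrics["accuracy"]
  }
  expect_lte(mean(cvAcc), mean(trainAcc))
})
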
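test_that("dichotomization follows direction with ties to the aggressive side", {
  onc <- MarkerRule("M", "oncogene", cutoff = 0.2)
  sup <- MarkerRule("M", "suppressor", cutoff = 0.2)
  expect_equal(dichotomize(0.3, onc), 1L)
  expect_equal(dichotomize(0.3, sup), 0L)
  expect_equal(dichotomize(0.1, onc), 0L)
  expect_equal(dichotomize(0.1, sup), 1L)
  expect_equal(dichotomize(0.2, onc), 1L)  # equality -> aggressive
  expect_equal(dichotomize(0.2, sup), 1L)
  expect_true(is.na(dichotomize(NA, onc)))
})

test_that("cutoff search returns the enumerated optimum on worked examples", {
  f <- searchOptimalCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1), "oncogene")
  expect_equal(f$cutoff, 3)
  expect_equal(f$accuracy, 1)

  f2 <- searchOptimalCutoff(c(1, 2, 3, 4), c(1, 1, 0, 0), "suppressor")
  expect_equal(f2$cutoff, 2)
  expect_equal(f2$accuracy, 1)

  # single-class labels are permitted; all-indolent is not representable in
  # the observed-value candidate scheme, so the best cutoff concedes the max
  f3 <- searchOptimalCutoff(c(1, 2, 3), c(0, 0, 0), "oncogene")
  expect_equal(f3$accuracy, 2 / 3)
  expect_equal(f3$cutoff, 3)

  expect_error(searchOptimalCutoff(c(2, 2, 2), c(0, 1, 0), "oncogene"),
               class = "wd_degenerate_marker")
})

test_that("cutoff search equals the exhaustive oracle on random instances", {
  set.seed(31)
  for (i in 1:150) {
    n <- sample(2:30, 1)
    vals <- sample(c(round(runif(n, 0, 1), 2), runif(n)))[seq_len(n)]
    labs <- rbinom(n, 1, runif(1, 0.2, 0.8))
    dir <- sample(c("oncogene", "suppressor"), 1)
    if (length(unique(vals)) < 2) next
    got <- searchOptimalCutoff(vals, labs, dir)
    want <- oracleCutoff(vals, labs, dir)
    expect_identical(got$cutoff, want$cutoff)
    expect_identical(got$accuracy, want$accuracy)
    # majority-accuracy floor, asserted against the oracle's own optimum
    expect_gte(got$accuracy, want$accuracy)
  }
})

test_that("weights are accuracy-proportional, normalized and scale-invariant", {
  expect_equal(unname(computeWeights(c(0.5, 0.5, 0.5))), rep(1 / 3, 3))
  expect_equal(computeWeights(0.9), 1.0)
  a <- c(0.724, 0.676, 0.667)
  w <- computeWeights(a)
  expect_equal(unname(w), a / sum(a), tolerance = 1e-15)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(computeWeights(3.7 * a), w, tolerance = 1e-12)
  expect_error(computeWeights(c(0.5, 0)), class = "wd_validation_error")
})

test_that("composite scores respect the weighted-sum algebra", {
  w <- computeWeights(c(0.724, 0.676, 0.667))
  expect_equal(compositeScore(c(1, 1, 1), w), 1)
  expect_equal(compositeScore(c(0, 0, 0), w), 0)
  s <- compositeScore(c(1, 1, 0), w)
  expect_equal(s, (0.724 + 0.676) / (0.724 + 0.676 + 0.667))
  expect_true(s >= 0.5)  # called aggressive
  expect_error(compositeScore(c(1, 0), w), class = "wd_validation_error")
  # missing-vote extension keeps the score in [0, 1]
  expect_true(is.na(compositeScore(c(1, NA, 0), w)))
  expect_equal(compositeScore(c(1, NA, 1), w, renormalizeMissing = TRUE), 1)
})

test_that("the decision rule calls aggressive at and above the threshold", {
  expect_equal(classifyScore(c(0.5, 0.49, 1.0, 0)),
               c("aggressive", "indolent", "aggressive", "indolent"))
  expect_equal(classifyScore(0.3, threshold = 0.3), "aggressive")
})

test_that("fitting a separable cohort reaches training accuracy 1", {
  se <- normalizeBatch(simulateCohort(separableConfig(
    nBatches = 2, batchShiftSd = 15, batchScaleRange = c(0.7, 1.3))))
  lab <- assignLabels(se)
  clf <- fitWD(se, lab, panelDirections)
  for (r in clf@rules) expect_equal(r@accuracy, 1)
  expect_equal(trainingAccuracy(clf, se, lab), 1)
})

test_that("a fit reproduces its own training accuracy (self-consistency)", {
  se <- normalizeBatch(simulateCohort(cohortConfig(
    nAggressive = 20, nIndolent = 30, seed = 14)))
  lab <- assignLabels(se)
  clf <- fitWD(se, lab, panelDirections)
  votes <- predict(clf, se, type = "votes")
  # per-marker vote accuracy equals the fitted alpha
  y <- as.integer(alignLabels(se, lab) == "aggressive")
  for (i in seq_along(clf@rules)) {
    mk <- clf@rules[[i]]@marker
    expect_equal(mean(votes[, mk] == y), clf@rules[[i]]@accuracy)
  }
})

test_that("score is monotone in each vote and bounded", {
  set.seed(19)
  for (i in 1:25) {
    k <- sample(1:6, 1)
    w <- computeWeights(runif(k, 0.1, 1))
    p <- rbinom(k, 1, 0.5)
    s <- compositeScore(p, w)
    expect_true(s >= 0 && s <= 1)
    for (j in which(p == 0)) {
      p2 <- p; p2[j] <- 1
      expect_gte(compositeScore(p2, w), s)
    }
  }
})

test_that("predictions are invariant to per-batch affine raw distortions", {
  cfg <- cohortConfig(nAggressive = 15, nIndolent = 25, nBatches = 3,
                      batchShiftSd = 0, batchScaleRange = c(1, 1), seed = 55)
  se <- simulateCohort(cfg)
  raw <- intensities(se)
  b <- batchIds(se)
  set.seed(56)
  distorted <- raw
  for (mk in rownames(raw)) for (bt in unique(b)) {
    sel <- b == bt
    distorted[mk, sel] <- runif(1, 0.5, 2) * raw[mk, sel] + runif(1, 0, 40)
  }
  lab <- assignLabels(se)
  n1 <- normalizeBatch(se)
  n2 <- normalizeBatch(makeSE(distorted, batch = b))
  clf1 <- fitWD(n1, lab, panelDirections)
  clf2 <- fitWD(n2, lab, panelDirections)
  expect_equal(predict(clf1, n1)$prediction, predict(clf2, n2)$prediction)
  expect_equal(predict(clf1, n1)$score, predict(clf2, n2)$score,
               tolerance = 1e-12)
})

test_that("auto direction mode picks the better-scoring orientation", {
  se <- normalizeBatch(simulateCohort(cohortConfig(
    nAggressive = 25, nIndolent = 35, seed = 61)))
  lab <- assignLabels(se)
  clf <- fitWD(se, lab, directions = "auto")
  ref <- fitWD(se, lab, panelDirections)
  # with real signal present, auto recovers at least the prior-knowledge fit
  for (i in seq_along(clf@rules))
    expect_gte(clf@rules[[i]]@accuracy, ref@rules[[i]]@accuracy)
})

test_that("classifier serialization round-trips as structured text", {
  se <- normalizeBatch(simulateCohort(cohortConfig(
    nAggressive = 10, nIndolent = 15, seed = 71)))
  lab <- assignLabels(se)
  clf <- fitWD(se, lab, panelDirections)
  path <- withr::local_tempfile(fileext = ".json")
  writeWDModel(clf, path)
  back <- readWDModel(path)
  expect_equal(back@weights, unname(clf@weights), tolerance = 1e-15)
  expect_equal(predict(back, se)$score, predict(clf, se)$score)
})

test_that("fit refuses raw tables and undersized classes", {
  se <- simulateCohort(cohortConfig(nAggressive = 10, nIndolent = 15,
                                    seed = 81))
  lab <- assignLabels(se)
  expect_error(fitWD(se, lab, panelDirections),
               class = "wd_validation_error")
  nse <- normalizeBatch(se)
  one <- lab
  one$label[one$label == "aggressive"][-1] <- "excluded"
  expect_error(fitWD(nse, one, panelDirections),
               class = "wd_validation_error")
  expect_error(fitWD(nse, lab, c(FGFR1 = "suppressor")),
               class = "wd_validation_error")
})
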
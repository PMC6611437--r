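test_that("median split assigns H strictly above the median, ties to L", {
  sp <- medianSplit(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(sp$split_value, 2.5)
  expect_equal(as.character(sp$groups$group), c("L", "L", "H", "H"))

  sp2 <- medianSplit(c(a = 1, b = 2, c = 3))
  expect_equal(sp2$split_value, 2)
  expect_equal(as.character(sp2$groups$group[2]), "L")

  set.seed(2)
  v <- rnorm(31)
  g <- medianSplit(v)$groups$group
  expect_lte(abs(sum(g == "H") - sum(g == "L")), 1)

  expect_error(medianSplit(rep(3, 5)), class = "wd_degenerate_split")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: flat at 1
  km2 <- kmEstimate(c(5, 8, 10), c(0, 0, 0))
  expect_true(all(km2$survival == 1))

  # censoring reduces the risk set without an event step
  km3 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km3$survival[km3$time == 3], (2 / 3) * (1 / 1) * 0)
})

test_that("uncensored Kaplan-Meier equals the empirical survival function", {
  set.seed(12)
  t <- sample(rexp(40, 0.1))
  km <- kmEstimate(t, rep(1, 40))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(t > km$time[i]))
})

test_that("coxph maximizes the in-repo Efron partial likelihood", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    x <- rnorm(n)
    t <- round(rexp(n, exp(0.8 * x)), 2)   # rounding can induce ties
    ev <- rep(1, n)
    fit <- suppressWarnings(coxFit(data.frame(x = x), t, ev))
    brute <- optimize(function(b) coxPartialLogLik(b, x, t, ev),
                      interval = c(-10, 10), maximum = TRUE,
                      tol = 1e-10)$maximum
    expect_equal(fit$coef, brute, tolerance = 1e-4)
  }
})

test_that("a factor with symmetric event experience gets coefficient ~0", {
  t <- rep(c(1, 2, 3, 4), 2)
  ev <- rep(1, 8)
  g <- rep(0:1, each = 4)
  fit <- coxFit(data.frame(g = g), t, ev)
  expect_equal(fit$coef, 0, tolerance = 1e-8)
  expect_equal(fit$z, fit$coef / fit$se, tolerance = 1e-6)
})

test_that("Cox sign agrees with the Kaplan-Meier ordering of two groups", {
  set.seed(44)
  t <- c(rexp(30, 1), rexp(30, 4))   # group 1 fails faster
  g <- rep(0:1, each = 30)
  fit <- coxFit(data.frame(g = g), t, rep(1, 60))
  expect_gt(fit$coef, 0)
  km <- kmEstimate(t, rep(1, 60), groups = g)
  s0 <- km$survival[km$group == "0"]
  t0 <- km$time[km$group == "0"]
  s1 <- km$survival[km$group == "1"]
  t1 <- km$time[km$group == "1"]
  # group with positive log-hazard has lower survival at the median time
  tm <- median(t)
  expect_gt(min(s0[t0 <= tm], 1), min(s1[t1 <= tm], 1))
})

test_that("perfect separation is flagged, never silent", {
  # all events in one arm occur before any in the other: monotone likelihood
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(fit <- coxFit(data.frame(g = g), t, rep(1, 8)),
                 "flagged")
  expect_true(fit$flagged)
})

test_that("Cox p-values are uniform under a permutation null", {
  set.seed(47)
  n <- 60
  t <- rexp(n, 0.2)
  ev <- rep(1, n)
  p <- replicate(500, {
    g <- sample(rep(0:1, each = n / 2))
    coxFit(data.frame(g = g), t, ev)$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("multivariate and univariate tables share the Table-2 shape", {
  se <- simulateCohort(cohortConfig(nAggressive = 25, nIndolent = 40,
                                    seed = 53))
  cl <- clinicalData(se)
  design <- data.frame(psa = cl$psa,
                       margin = as.integer(cl$margin == "positive"))
  uni <- coxFit(design, cl$time_months, cl$event, "univariate")
  multi <- coxFit(design, cl$time_months, cl$event, "multivariate")
  expect_equal(colnames(uni),
               c("factor", "coef", "se", "z", "p", "fit_type", "flagged"))
  expect_equal(nrow(uni), 2)
  expect_equal(nrow(multi), 2)
  expect_equal(multi$fit_type, rep("multivariate", 2))
  expect_equal(uni$z, uni$coef / uni$se, tolerance = 1e-6)
  expect_error(coxFit(data.frame(k = rep(1, 65)), cl$time_months, cl$event),
               class = "wd_validation_error")
})

test_that("Cox recovers a known log-hazard ratio", {
  set.seed(59)
  est <- cover <- numeric(40)
  for (r in seq_len(40)) {
    x <- rnorm(120)
    t <- rexp(120, 0.1 * exp(x))
    fit <- suppressWarnings(coxFit(data.frame(x = x), t, rep(1, 120)))
    est[r] <- fit$coef
    cover[r] <- abs(fit$coef - 1) <= 1.96 * fit$se
  }
  expect_lt(abs(mean(est) - 1), 0.1)
  expect_gt(mean(cover), 0.85)
})

test_that("pairwise correlations match direct arithmetic and flag degeneracy", {
  m <- correlationMatrix(data.frame(a = c(1, 2, 3), b = c(2, 4, 6),
                                    c = c(6, 4, 2)))
  expect_equal(unname(diag(m)), c(1, 1, 1))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))

  expect_equal(correlationMatrix(
    data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4)))["x", "y"], 0.8)

  z <- correlationMatrix(data.frame(x = 1:4, k = rep(2, 4)))
  expect_true(is.na(z["x", "k"]))
  expect_true("x:k" %in% attr(z, "undefined"))

  # pairwise-complete handling with missing values
  w <- correlationMatrix(data.frame(x = c(1, 2, 3, NA, 5),
                                    y = c(2, 4, 6, 8, NA)))
  expect_equal(w["x", "y"], 1)
})

test_that("median-split marker survival reports Cox and log-rank p-values", {
  se <- normalizeBatch(simulateCohort(cohortConfig(
    nAggressive = 30, nIndolent = 50, seed = 67)))
  ms <- markerSurvival(se)
  expect_equal(ms$summary$marker, rownames(se))
  expect_true(all(ms$summary$p_cox >= 0 & ms$summary$p_cox <= 1))
  expect_true(all(abs(ms$summary$n_H - ms$summary$n_L) <=
                    ncol(se)))
  expect_equal(sort(names(ms$curves)), sort(rownames(se)))
  # significance convention: p <= 0.05 claims significance; with planted
  # signal at these sizes the strongest marker separates the split groups
  expect_lte(min(ms$summary$p_cox), 0.05)
})
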
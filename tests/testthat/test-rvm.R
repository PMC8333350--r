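test_that("the RVM separates a separable toy problem with a sparse solution", {
  set.seed(31)
  X <- rbind(matrix(rnorm(40 * 5, -1), 40, 5), matrix(rnorm(40 * 5, 1), 40, 5))
  y <- rep(c(0, 1), each = 40)
  fit <- fitRVM(X, y)
  p <- predictRVM(fit, X)
  expect_true(all(p > 0 & p < 1))
  expect_equal(aucFromScores(p[y == 1], p[y == 0]), 1)
  # relevance vectors are a strict subset of the training points
  expect_lte(sum(fit$relevanceIndex > 0), nrow(X))
  expect_lt(sum(fit$relevanceIndex > 0), nrow(X))
  # a positive-class relevance vector is classified as positive
  rvPos <- which(fit$relevanceIndex > 40)[1]
  if (!is.na(rvPos)) {
    idx <- fit$relevanceIndex[rvPos]
    expect_gt(predictRVM(fit, X[idx, , drop = FALSE]), 0.5)
  }
  expect_error(fitRVM(X, rep(1, 80)), "both classes")
  expect_error(predictRVM(fit, X[, 1:3]), "width")
})

test_that("RVM predictions are monotone along the discriminant direction", {
  set.seed(32)
  X <- rbind(matrix(rnorm(30 * 4, -1), 30, 4), matrix(rnorm(30 * 4, 1), 30, 4))
  y <- rep(c(0, 1), each = 30)
  fit <- fitRVM(X, y)
  dirv <- colMeans(X[y == 1, ]) - colMeans(X[y == 0, ])
  probe <- outer(seq(-3, 3, length.out = 13), dirv)
  p <- predictRVM(fit, probe)
  # monotone along the discriminant; sigmoid may saturate at the extremes
  expect_true(all(diff(p) >= 0))
  expect_gt(p[13], p[1])
  mid <- p[5:9]
  expect_true(all(diff(mid) > 0))
})

test_that("duplicated feature columns leave predictions nearly unchanged", {
  set.seed(33)
  X <- rbind(matrix(rnorm(25 * 3, -1.5), 25, 3),
             matrix(rnorm(25 * 3, 1.5), 25, 3))
  y <- rep(c(0, 1), each = 25)
  base <- predictRVM(fitRVM(X, y), X)
  dup <- predictRVM(fitRVM(cbind(X, X), y), cbind(X, X))
  # the linear kernel sees a doubled Gram matrix; the evidence-maximised
  # weights compensate, so ranking and probabilities agree closely
  expect_equal(cor(base, dup), 1, tolerance = 1e-3)
  expect_lt(max(abs(base - dup)), 0.1)
})

test_that("RVM out-of-bag behaviour is null-calibrated on permuted labels", {
  set.seed(34)
  n <- 100
  X <- matrix(rnorm(2 * n * 6), 2 * n, 6)
  y <- sample(rep(c(0, 1), n))       # labels independent of features
  tr <- sample(2 * n, n)
  fit <- fitRVM(X[tr, ], y[tr])
  p <- predictRVM(fit, X[-tr, ])
  auc <- aucFromScores(p[y[-tr] == 1], p[y[-tr] == 0])
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("the 0.632+ weight follows the clipped overfitting-rate formula", {
  expect_equal(omegaWeight(0.8, 0.8), 0.632)
  # complete overfitting (R = 1): 0.632/(1 - 0.368) = 1 exactly
  expect_equal(omegaWeight(1.0, 0.5), 1)
  expect_equal(omegaWeight(0.7, 0.9), 0.632)      # oob > resub => R = 0
  expect_equal(omegaWeight(0.4, 0.3), 0.632)      # resub below chance
  # interior value: R = (0.9-0.7)/(0.9-0.5) = 0.5
  expect_equal(omegaWeight(0.9, 0.7), 0.632 / (1 - 0.368 * 0.5))
  w <- omegaWeight(runif(50, 0.5, 1), runif(50))
  expect_true(all(w >= 0.632 & w <= 1))
  expect_error(omegaWeight(1.2, 0.5), "0, 1")
})

test_that("0.632+ bootstrap mechanics on a toy cohort", {
  maps <- list(AD = adEffectMap(1))
  cl <- simulateClinicalCohort(
    simulationSpec(nPerGroup = c(HC = 20, AD = 15), effectMaps = maps,
                   noiseSd = 0.05, seed = 35), name = "toy")
  r <- bootstrap632Auc(cl$cohort, c("HC", "AD"), b = 2L, seed = 1L)
  expect_equal(r$b, 2L)
  expect_equal(r$poolSize, 35L)
  # convexity: each blended value lies between its two components
  lo <- pmin(r$aucResub, r$aucOob); hi <- pmax(r$aucResub, r$aucOob)
  expect_true(all(r$blended >= lo - 1e-12 & r$blended <= hi + 1e-12))
  expect_gte(r$aucBootstrap, min(r$blended))
  expect_lte(r$aucBootstrap, max(r$blended))
  # the aggregate recomputes bit-exactly from the stored components
  expect_identical(r$aucBootstrap,
                   mean(r$omega * r$aucOob + (1 - r$omega) * r$aucResub))
  # reproducibility
  r2 <- bootstrap632Auc(cl$cohort, c("HC", "AD"), b = 2L, seed = 1L)
  expect_identical(r$blended, r2$blended)
})

test_that("cross-cohort generalization scores external cohorts sensibly", {
  maps <- list(AD = adEffectMap(1))
  mk <- function(seed, name)
    simulateClinicalCohort(
      simulationSpec(nPerGroup = c(HC = 40, AD = 30), effectMaps = maps,
                     seed = seed), name = name)$cohort
  train <- mk(36, "train"); same <- mk(37, "same")
  nullC <- simulateClinicalCohort(
    simulationSpec(nPerGroup = c(HC = 40, AD = 30),
                   effectMaps = list(AD = adEffectMap(0)), seed = 38),
    name = "nullc")$cohort
  r <- bootstrap632Auc(train, c("HC", "AD"), b = 10L, seed = 2L,
                       keepModels = TRUE)
  gen <- crossCohortGeneralization(r, list(same, nullC))
  expect_equal(colnames(gen$aucs), c("same", "nullc"))
  # same generative law: generalization close to the within-cohort oob AUC
  expect_lt(abs(gen$summary$auc[1] - mean(r$aucOob)), 0.1)
  # zero-effect cohort: CI covers chance
  expect_lte(gen$summary$lower[2], 0.5)
  expect_gte(gen$summary$upper[2], 0.5)
  expect_error(crossCohortGeneralization(
    bootstrap632Auc(train, c("HC", "AD"), b = 2L, seed = 3L), list(same)),
    "keepModels")
})

test_that("paired AUC difference CIs behave and are antisymmetric", {
  a <- c(0.8, 0.85, 0.9); b <- a
  d <- aucDifferenceCI(a, b)
  expect_equal(c(d$ci$lower, d$ci$upper), c(0, 0))
  expect_false(d$significant)
  b2 <- a - 0.05
  d2 <- aucDifferenceCI(a, b2)
  expect_true(d2$significant)
  expect_gt(d2$ci$lower, 0)
  d3 <- aucDifferenceCI(b2, a)
  expect_equal(c(d3$ci$lower, d3$ci$upper), -c(d2$ci$upper, d2$ci$lower))
  # spanning zero (the not-significant pattern of weak contrasts)
  d4 <- aucDifferenceCI(c(0.70, 0.72, 0.74), c(0.73, 0.71, 0.74))
  expect_false(d4$significant)
  expect_error(aucDifferenceCI(a, a[1:2]), "equal iteration")
})
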
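test_that("observed deviation is the mean squared reconstruction error", {
  x <- rnorm(101); expect_equal(observedDeviation(x, x), 0)
  expect_equal(observedDeviation(rep(1, 101), rep(0, 101)), 1)
  expect_equal(observedDeviation(c(0.5, -0.5), c(0, 0)), 0.25)
  expect_error(observedDeviation(rnorm(101), rnorm(100)), "length")
  # matrix form scores one subject per row
  X <- matrix(rnorm(5 * 101), 5); Xh <- matrix(rnorm(5 * 101), 5)
  expect_equal(observedDeviation(X, Xh), rowMeans((X - Xh)^2))
})

test_that("region deviations decompose the observed deviation exactly", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(101); xh <- rnorm(101)
    d <- regionDeviations(x, xh)
    expect_true(all(d >= 0))
    expect_identical(mean(d), observedDeviation(x, xh))
  }
  x <- c(1, rep(0, 100)); xh <- rep(0, 101)
  expect_equal(regionDeviations(x, xh), c(1, rep(0, 100)))
  expect_equal(regionDeviations(x, xh, signed = TRUE), x)
  expect_equal(regionDeviations(x, x), rep(0, 101))
})

bruteDelta <- function(a, b) {
  s <- 0
  for (ai in a) for (bj in b) s <- s + sign(ai - bj)
  s / (length(a) * length(b))
}
bruteAuc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

test_that("Cliff's delta matches its brute-force pairwise oracle", {
  expect_equal(cliffsDelta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffsDelta(c(2, 4, 9), c(2, 4, 9)), 0)
  expect_equal(cliffsDelta(c(3, 1), 2), 0)
  set.seed(22)
  for (i in 1:50) {
    a <- sample(0:8, sample(2:9, 1), replace = TRUE)  # ties likely
    b <- sample(0:8, sample(2:9, 1), replace = TRUE)
    expect_equal(cliffsDelta(a, b), bruteDelta(a, b), tolerance = 1e-12)
    expect_equal(cliffsDelta(a, b), -cliffsDelta(b, a), tolerance = 1e-12)
    expect_true(abs(cliffsDelta(a, b)) <= 1)
  }
  expect_error(cliffsDelta(numeric(0), 1), "non-empty")
})

test_that("AUC matches the pairwise probability oracle and the delta identity", {
  expect_equal(aucFromScores(c(2, 3), c(0, 1)), 1)
  expect_equal(aucFromScores(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(aucFromScores(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(23)
  for (i in 1:50) {
    pos <- rnorm(sample(2:10, 1)); neg <- rnorm(sample(2:10, 1))
    expect_equal(aucFromScores(pos, neg), bruteAuc(pos, neg),
                 tolerance = 1e-12)
    expect_equal(aucFromScores(pos, neg),
                 (cliffsDelta(pos, neg) + 1) / 2, tolerance = 1e-15)
  }
})

test_that("percentile CIs follow the linear-interpolation convention", {
  ci <- percentileCI(1:1000)
  expect_equal(ci$lower, 25.975)
  expect_equal(ci$upper, 975.025)
  expect_equal(ci$point, 500.5)
  same <- percentileCI(rep(3.3, 10))
  expect_equal(c(same$lower, same$upper), c(3.3, 3.3))
  shuffled <- percentileCI(sample(1:1000))
  expect_equal(c(shuffled$lower, shuffled$upper), c(ci$lower, ci$upper))
  expect_error(percentileCI(1), ">= 2")
  ci90 <- percentileCI(1:1000, level = 0.9)
  expect_equal(ci90$lower, unname(quantile(1:1000, 0.05, type = 7)))
})

test_that("deviation scoring returns one non-negative score per subject", {
  co <- toyReference(n = 20, seed = 24)
  m <- trainAAE(co, fastConfig(seed = 9))
  sc <- scoreDeviations(co, m)
  expect_equal(nrow(sc), 20L)
  expect_true(all(sc$observed_deviation >= 0))
  reg <- attr(sc, "regionDeviations")
  expect_equal(dim(reg), c(20L, 101L))
  expect_equal(unname(rowMeans(reg)), sc$observed_deviation)
})

test_that("bootstrap evaluation plumbing produces well-formed results", {
  ref <- toyReference(n = 50, seed = 25)
  maps <- list(AD = adEffectMap(1))
  cl <- simulateClinicalCohort(
    simulationSpec(nPerGroup = c(HC = 12, AD = 12), effectMaps = maps,
                   seed = 26), name = "toyclin")
  nb <- bootstrapNormativeEvaluation(ref, cl$cohort, fastConfig(),
                                     B = 2L, seed = 1L)
  expect_equal(nb$B, 2L)
  expect_equal(dim(nb$groupMeans$toyclin), c(2L, 2L))
  dv <- deviationSummary(nb)
  expect_equal(nrow(dv), 2L)
  expect_true(all(dv$lower <= dv$mean_deviation + 1e-12))
  expect_true(all(dv$upper >= dv$mean_deviation - 1e-12))
  au <- aucSummary(nb)
  expect_equal(au$group, "AD")
  expect_true(all(au$auc >= 0 & au$auc <= 1))
  eff <- regionEffectSummary(nb)
  expect_equal(nrow(eff), 101L)
  expect_true(all(abs(eff$delta) <= 1))
  gd <- groupDifferenceSummary(nb)
  expect_equal(gd$contrast, "HC-AD")
  # errors
  expect_error(bootstrapNormativeEvaluation(ref, cl$cohort, fastConfig(),
                                            B = 0L), "B must be")
  onlyAD <- subsetGroups(cl$cohort, "AD")
  expect_error(bootstrapNormativeEvaluation(ref, onlyAD, fastConfig(),
                                            B = 1L), "HC group")
  expect_error(bootstrapNormativeEvaluation(cl$cohort, cl$cohort,
                                            fastConfig(), B = 1L),
               "HC subjects only")
})

test_that("bootstrap evaluation is reproducible given the master seed", {
  ref <- toyReference(n = 40, seed = 27)
  cl <- simulateClinicalCohort(
    simulationSpec(nPerGroup = c(HC = 10, AD = 10),
                   effectMaps = list(AD = adEffectMap(1)), seed = 28),
    name = "c")
  a <- bootstrapNormativeEvaluation(ref, cl$cohort, fastConfig(), B = 2L,
                                    seed = 5L)
  b <- bootstrapNormativeEvaluation(ref, cl$cohort, fastConfig(), B = 2L,
                                    seed = 5L)
  expect_identical(a$groupMeans, b$groupMeans)
  expect_identical(a$regionDeltas, b$regionDeltas)
})
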
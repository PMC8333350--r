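test_that("network shapes follow the architecture contract", {
  m <- buildAAE(aaeConfig(seed = 1))
  # encoder 101 -> 100 -> 100 -> 20
  expect_equal(dim(m@encoder[[1]]$W), c(101L, 100L))
  expect_equal(dim(m@encoder[[3]]$W), c(100L, 20L))
  # decoder input = 20 latent + 27 age + 2 sex = 49
  expect_equal(dim(m@decoder[[1]]$W), c(49L, 100L))
  expect_equal(dim(m@decoder[[3]]$W), c(100L, 101L))
  # discriminator 20 -> 100 -> 100 -> 1
  expect_equal(dim(m@discriminator[[1]]$W), c(20L, 100L))
  expect_equal(dim(m@discriminator[[3]]$W), c(100L, 1L))
  # encoder parameter count: 101*100+100 + 100*100+100 + 100*20+20
  ns <- asNamespace("aaenorm")
  expect_equal(ns$mlpParamCount(m@encoder), 22320)
})

test_that("initialisation is deterministic given the seed", {
  a <- buildAAE(aaeConfig(seed = 7))
  b <- buildAAE(aaeConfig(seed = 7))
  expect_identical(a@encoder, b@encoder)
  expect_identical(a@decoder, b@decoder)
  expect_false(identical(buildAAE(aaeConfig(seed = 8))@encoder, a@encoder))
})

test_that("forward passes honour zero-weight and dimension contracts", {
  m <- buildAAE(aaeConfig(seed = 1))
  zeroed <- m
  for (slot in c("encoder", "decoder", "discriminator")) {
    net <- slot(zeroed, slot)
    for (l in seq_along(net)) { net[[l]]$W[] <- 0; net[[l]]$b[] <- 0 }
    slot(zeroed, slot) <- net
  }
  x <- rnorm(101)
  expect_equal(unname(aaeEncode(zeroed, x)[1, ]), rep(0, 20))
  cond <- cbind(oneHotAge(50L), oneHotSex("male"))
  expect_equal(unname(aaeDecode(zeroed, rep(0, 20), cond)[1, ]), rep(0, 101))
  expect_equal(aaeDiscriminate(zeroed, rep(0, 20)), 0.5)
  # dimensions
  expect_equal(ncol(aaeEncode(m, x)), 20L)
  expect_equal(ncol(aaeDecode(m, rnorm(20), cond)), 101L)
  p <- aaeDiscriminate(m, matrix(rnorm(100), 5, 20))
  expect_true(all(p > 0 & p < 1))
  expect_error(aaeEncode(m, rnorm(100)), "width")
  expect_error(aaeDecode(m, rnorm(20), cond[, -1, drop = FALSE]), "width")
  badCond <- cond; badCond[1, 1:27] <- 0
  expect_error(aaeDecode(m, rnorm(20), badCond), "one-hot")
})

test_that("encoding is continuous in its input", {
  m <- buildAAE(aaeConfig(seed = 2))
  x <- rnorm(101)
  h0 <- aaeEncode(m, x)
  for (eps in 10^(-(3:6))) {
    h1 <- aaeEncode(m, x + eps * rnorm(101))
    expect_lt(sqrt(sum((h1 - h0)^2)), eps * 1e3)
  }
})

test_that("backpropagation matches finite differences", {
  ns <- asNamespace("aaenorm")
  set.seed(10)
  net <- ns$mlpInit(c(6, 5, 3))
  X <- matrix(rnorm(4 * 6), 4, 6)
  Y <- matrix(rnorm(4 * 3), 4, 3)
  slope <- 0.01
  lossOf <- function(nn) mean((ns$mlpForward(nn, X, slope)$out - Y)^2)
  f <- ns$mlpForward(net, X, slope)
  g <- ns$mlpBackward(net, f, 2 * (f$out - Y) / length(Y), slope)
  eps <- 1e-6
  for (l in 1:2) {
    gw <- g$gW[[l]]
    for (k in sample(length(net[[l]]$W), 5)) {
      n2 <- net; n2[[l]]$W[k] <- n2[[l]]$W[k] + eps
      expect_equal(gw[k], (lossOf(n2) - lossOf(net)) / eps, tolerance = 1e-4)
    }
  }
})

test_that("the cyclical learning rate follows the stated decay rule", {
  cfg <- aaeConfig()         # base 1e-4, max 5e-3, gamma 0.98
  stepSize <- 32L
  lr <- function(s) cyclicalLearningRate(s, cfg, batchesPerEpoch = 8L)
  expect_equal(lr(0), 1e-4)
  expect_equal(lr(stepSize), 5e-3)                 # first peak
  expect_equal(lr(2 * stepSize), 1e-4)             # back to base
  expect_equal(lr(3 * stepSize), 1e-4 + 0.98 * (5e-3 - 1e-4))  # second peak
  expect_equal(lr(5 * stepSize), 1e-4 + 0.98^2 * (5e-3 - 1e-4))
  # triangular shape: linear halfway up
  expect_equal(lr(stepSize / 2), 1e-4 + 0.5 * (5e-3 - 1e-4))
  # explicit cycle step size overrides the epoch-derived default
  cfg2 <- aaeConfig(cycleStepSize = 10L)
  expect_equal(cyclicalLearningRate(10L, cfg2), 5e-3)
})

test_that("training refuses non-HC cohorts and is reproducible", {
  co <- toyReference(n = 48, seed = 13)
  mixed <- co
  SummarizedExperiment::colData(mixed)$group[1] <- "AD"
  expect_error(trainAAE(mixed, fastConfig()), "HC subjects only")
  m1 <- trainAAE(co, fastConfig(seed = 3))
  m2 <- trainAAE(co, fastConfig(seed = 3))
  expect_identical(m1@encoder, m2@encoder)
  expect_identical(m1@trainLog, m2@trainLog)
  expect_equal(nrow(m1@trainLog), 8L)   # one row per epoch
  expect_true(all(is.finite(m1@trainLog$recon_loss)))
})

test_that("reconstruction error decreases over training", {
  co <- toyReference(n = 64, seed = 14)
  m <- trainAAE(co, aaeConfig(epochs = 40L, batchSize = 32L, seed = 4))
  log <- m@trainLog$recon_loss
  expect_lt(log[length(log)], log[1])
  # non-increasing trend in 10-epoch medians
  med <- tapply(log, (seq_along(log) - 1) %/% 10, median)
  expect_true(all(diff(med) < 0.05))
})

test_that("a perfectly conditionable cohort is reconstructed almost exactly", {
  # no noise: features are a deterministic function of (age, sex), which the
  # decoder receives one-hot, so near-zero reconstruction error is attainable
  spec <- simulationSpec(nPerGroup = c(HC = 512), noiseSd = 0, tivSd = 0,
                         seed = 301)
  co <- simulateReferenceCohort(spec)
  # one-epoch cycles decay the LR amplitude fast enough for the final
  # low-noise phase to settle to the representable optimum
  m <- trainAAE(co, aaeConfig(seed = 5, batchSize = 64L,
                              cycleStepSize = 8L))
  expect_lt(m@trainLog$recon_loss[200], 1e-3)
})

test_that("scoring plumbing: identity stub gives zero deviation", {
  co <- toyReference(n = 12, seed = 15)
  rel <- relativeVolumes(co)
  scaler <- fitScaler(rel)
  m <- buildAAE(aaeConfig(encoderHidden = c(101L, 101L),
                          latentDim = 101L,
                          decoderHidden = c(101L, 101L), seed = 1))
  idLayer <- function(d_in, d_out, offset = 0L) {
    W <- matrix(0, d_in, d_out)
    for (i in seq_len(min(d_in - offset, d_out)))
      W[i + offset, i] <- 1
    list(W = W, b = numeric(d_out))
  }
  # encoder = identity on the 101-dim subspace; decoder picks the latent
  # part of (h, condition) back out; ReLU regions stay linear for x >= 0
  m@encoder <- list(idLayer(101, 101), idLayer(101, 101), idLayer(101, 101))
  m@decoder <- list(idLayer(130, 101), idLayer(101, 101), idLayer(101, 101))
  m@scaler <- unclass(scaler)
  r <- reconstructCohort(co, m)
  pos <- r$x >= 0          # identity holds on the non-negative orthant
  expect_equal(r$xhat[pos], r$x[pos], tolerance = 1e-10)
  dev <- regionDeviations(r$x, r$xhat)
  expect_true(all(dev[pos] < 1e-20))
})

test_that("model artefacts round-trip exactly and detect tampering", {
  co <- toyReference(n = 32, seed = 16)
  m <- trainAAE(co, fastConfig(seed = 6))
  path <- withr::local_tempfile(fileext = ".rds")
  saveAAEModel(m, path)
  back <- readAAEModel(path)
  expect_identical(back@encoder, m@encoder)
  expect_identical(back@scaler, m@scaler)
  expect_identical(back@trainLog, m@trainLog)
  # tamper with the artefact: checksum must refuse it
  saveRDS(list(oops = 1), path)
  expect_error(readAAEModel(path), "checksum")
})

test_that("scoring is deterministic and guards the atlas", {
  co <- toyReference(n = 24, seed = 17)
  m <- trainAAE(co, fastConfig(seed = 2))
  a <- reconstructCohort(co, m)
  b <- reconstructCohort(co, m)
  expect_identical(a$xhat, b$xhat)
  m2 <- m
  m2@atlas <- m@atlas[c(2:101, 1), ]
  expect_error(reconstructCohort(co, m2), "atlas")
  expect_error(reconstructCohort(co, buildAAE(aaeConfig())), "scaler")
})

test_that("decoder conditioning responds to the age bits", {
  # steep age slopes make age a strong predictor; a trained decoder must
  # use the age bits, so flipping them changes the reconstruction
  m <- deskModel()
  co <- deskReference()
  r <- reconstructCohort(co, m)
  h <- r$h[1:20, , drop = FALSE]
  condYoung <- cbind(oneHotAge(rep(47L, 20)), oneHotSex(rep("male", 20)))
  condOld <- cbind(oneHotAge(rep(73L, 20)), oneHotSex(rep("male", 20)))
  dy <- aaeDecode(m, h, condYoung)
  do <- aaeDecode(m, h, condOld)
  expect_gt(mean(abs(dy - do)), 0.05)
})
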
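#' Configuration of the adversarial autoencoder
#'
#' Architecture and optimisation settings of the conditioned adversarial
#' autoencoder (AAE). The defaults are the reference configuration: a
#' 101-dimensional input, encoder and decoder with two 100-neuron hidden
#' layers, a 20-dimensional latent code with a standard-normal prior, a
#' discriminator of the same shape, leaky-ReLU hidden activations, Adam
#' optimisers sharing a decaying triangular cyclical learning-rate schedule
#' (base 0.0001, peak 0.005, amplitude decay gamma 0.98 per cycle), 200
#' epochs with minibatches of 256.
#'
#' @param inputDim Number of input features (regions).
#' @param encoderHidden,decoderHidden,discriminatorHidden Integer vectors of
#'   hidden-layer widths.
#' @param latentDim Size of the latent code.
#' @param conditionDim Width of the demographic conditioning vector (27 age
#'   + 2 sex one-hot positions).
#' @param leakySlope Negative slope of the leaky-ReLU hidden activations.
#' @param epochs,batchSize Training schedule.
#' @param baseLr,maxLr,lrGamma Cyclical learning-rate bounds and per-cycle
#'   amplitude decay.
#' @param cycleStepSize Half-period of the triangular cycle, in minibatches;
#'   \code{NULL} means 4 epochs' worth of batches.
#' @param advWeight Weight of the adversarial (generator) loss relative to
#'   the reconstruction loss.
#' @param advLrScale Factor applied to the shared cyclical learning rate in
#'   the discriminator and generator phases. The reconstruction phase uses
#'   the schedule as-is; the adversarial game needs a cooler step size to
#'   reach equilibrium instead of oscillating (see the methods vignette).
#' @param discSteps Discriminator updates per minibatch (each with fresh
#'   prior samples) before the single generator update.
#' @param seed Integer seed controlling initialisation, shuffling and prior
#'   sampling; training is deterministic given it.
#' @return A list of class \code{"AAEConfig"}.
#' @export
aaeConfig <- function(inputDim = 101L,
                      encoderHidden = c(100L, 100L),
                      latentDim = 20L,
                      decoderHidden = c(100L, 100L),
                      discriminatorHidden = c(100L, 100L),
                      conditionDim = 29L,
                      leakySlope = 0.01,
                      epochs = 200L,
                      batchSize = 256L,
                      baseLr = 1e-4,
                      maxLr = 5e-3,
                      lrGamma = 0.98,
                      cycleStepSize = NULL,
                      advWeight = 1.0,
                      advLrScale = 0.2,
                      discSteps = 2L,
                      seed = 42L) {
  stopifnot(inputDim > 0, latentDim > 0, all(encoderHidden > 0),
            all(decoderHidden > 0), all(discriminatorHidden > 0),
            epochs >= 1, batchSize >= 1)
  if (!(baseLr < maxLr)) stop("baseLr must be < maxLr")
  if (lrGamma <= 0 || lrGamma > 1) stop("lrGamma must be in (0, 1]")
  structure(list(inputDim = as.integer(inputDim),
                 encoderHidden = as.integer(encoderHidden),
                 latentDim = as.integer(latentDim),
                 decoderHidden = as.integer(decoderHidden),
                 discriminatorHidden = as.integer(discriminatorHidden),
                 conditionDim = as.integer(conditionDim),
                 leakySlope = leakySlope, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), baseLr = baseLr,
                 maxLr = maxLr, lrGamma = lrGamma,
                 cycleStepSize = cycleStepSize, advWeight = advWeight,
                 advLrScale = advLrScale, discSteps = as.integer(discSteps),
                 seed = as.integer(seed)),
            class = "AAEConfig")
}

#' AAEModel: a (trained) conditioned adversarial autoencoder
#'
#' Holds the weights of the three sub-networks (encoder, condition-aware
#' decoder, discriminator), the \code{AAEConfig} used, the robust
#' \code{ScalerParams} fitted on the training set (the scaler is part of
#' the model), the atlas, and the per-epoch training log.
#'
#' @slot config The \code{AAEConfig}.
#' @slot encoder,decoder,discriminator Layer lists (weights and biases).
#' @slot scaler \code{ScalerParams} or empty list before training.
#' @slot atlas Atlas data.frame.
#' @slot trainLog data.frame with one row per epoch: reconstruction loss,
#'   discriminator loss, generator loss, learning rate.
#' @export
setClass("AAEModel", representation(config = "list", encoder = "list",
                                    decoder = "list",
                                    discriminator = "list",
                                    scaler = "list", atlas = "data.frame",
                                    trainLog = "data.frame"))

setValidity("AAEModel", function(object) {
  cfg <- object@config
  enc <- object@encoder
  if (!length(enc)) return(TRUE)
  sizes <- c(cfg$inputDim, cfg$encoderHidden, cfg$latentDim)
  for (l in seq_along(enc))
    if (!all(dim(enc[[l]]$W) == c(sizes[l], sizes[l + 1L])))
      return(sprintf("encoder layer %d has wrong shape", l))
  TRUE
})

setMethod("show", "AAEModel", function(object) {
  cfg <- object@config
  cat(sprintf("AAEModel: %d -> [%s] -> %d latent; decoder conditioned on %d demographics\n",
              cfg$inputDim, paste(cfg$encoderHidden, collapse = ","),
              cfg$latentDim, cfg$conditionDim))
  cat(sprintf("parameters: encoder %d, decoder %d, discriminator %d\n",
              mlpParamCount(object@encoder), mlpParamCount(object@decoder),
              mlpParamCount(object@discriminator)))
  if (nrow(object@trainLog))
    cat(sprintf("trained %d epochs; final reconstruction loss %.4g\n",
                nrow(object@trainLog),
                object@trainLog$recon_loss[nrow(object@trainLog)]))
  else cat("untrained (freshly initialised weights)\n")
})

#' Build an untrained AAE from a configuration
#'
#' Initialises the encoder (input -> hidden -> latent, linear latent), the
#' conditioned decoder (latent + 29 demographic bits -> hidden -> input,
#' linear output) and the discriminator (latent -> hidden -> 1 logit).
#' Weights use a fan-in-scaled uniform scheme, seeded by the config.
#'
#' @param config An \code{AAEConfig}.
#' @param atlas Atlas data.frame (stored with the model).
#' @return An \linkS4class{AAEModel} with freshly initialised weights.
#' @export
buildAAE <- function(config = aaeConfig(), atlas = dkAsegAtlas()) {
  stopifnot(inherits(config, "AAEConfig"))
  set.seed(config$seed)
  enc <- mlpInit(c(config$inputDim, config$encoderHidden, config$latentDim))
  dec <- mlpInit(c(config$latentDim + config$conditionDim,
                   config$decoderHidden, config$inputDim))
  dis <- mlpInit(c(config$latentDim, config$discriminatorHidden, 1L))
  new("AAEModel", config = unclass(config), encoder = enc, decoder = dec,
      discriminator = dis, scaler = list(), atlas = atlas,
      trainLog = data.frame())
}

#' Encode normalised features into the latent space
#'
#' Deterministic forward pass through the encoder; the latent layer has a
#' linear activation.
#'
#' @param model An \linkS4class{AAEModel}.
#' @param z Numeric matrix (subjects x inputDim) of normalised features, or
#'   a single feature vector.
#' @return Matrix of latent codes (subjects x latentDim).
#' @export
aaeEncode <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, 1L)
  if (ncol(z) != model@config$inputDim)
    stop("input width must be ", model@config$inputDim)
  mlpForward(model@encoder, z, model@config$leakySlope)$out
}

#' Decode latent codes with demographic conditioning
#'
#' Deterministic forward pass through the decoder on the concatenation of
#' the latent code and the (age, sex) one-hot condition vector; linear
#' output.
#'
#' @param model An \linkS4class{AAEModel}.
#' @param h Matrix of latent codes (subjects x latentDim).
#' @param condition Matrix of condition vectors (subjects x 29), each row
#'   one age bit and one sex bit set.
#' @return Matrix of reconstructions (subjects x inputDim).
#' @export
aaeDecode <- function(model, h, condition) {
  if (!is.matrix(h)) h <- matrix(h, 1L)
  if (!is.matrix(condition)) condition <- matrix(condition, 1L)
  cfg <- model@config
  if (ncol(h) != cfg$latentDim) stop("latent width must be ", cfg$latentDim)
  if (ncol(condition) != cfg$conditionDim)
    stop("condition width must be ", cfg$conditionDim)
  bad <- rowSums(condition[, 1:27, drop = FALSE]) != 1 |
    rowSums(condition[, 28:29, drop = FALSE]) != 1
  if (any(bad))
    stop("malformed condition vector: each one-hot block must have exactly one 1")
  mlpForward(model@decoder, cbind(h, condition), cfg$leakySlope)$out
}

#' Discriminator probability that a latent sample came from the prior
#'
#' @param model An \linkS4class{AAEModel}.
#' @param z Matrix (samples x latentDim) of latent-space points.
#' @return Vector of probabilities in (0, 1).
#' @export
aaeDiscriminate <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, 1L)
  if (ncol(z) != model@config$latentDim)
    stop("latent width must be ", model@config$latentDim)
  as.numeric(sigmoid(mlpForward(model@discriminator, z,
                                model@config$leakySlope)$out))
}

#' Decaying triangular cyclical learning rate
#'
#' Triangular wave between \code{baseLr} and \code{baseLr + amplitude},
#' where the amplitude of cycle \eqn{k} (0-based) is
#' \eqn{(maxLr - baseLr)\,\gamma^k}: the first peak reaches \code{maxLr}
#' exactly, later peaks decay geometrically. One cycle spans
#' \code{2 * cycleStepSize} minibatch steps.
#'
#' @param step 0-based minibatch index (vectorised).
#' @param config An \code{AAEConfig}.
#' @param batchesPerEpoch Used only to resolve the default cycle step size
#'   (4 epochs' worth of batches) when \code{config$cycleStepSize} is NULL.
#' @return Learning rate(s).
#' @examples
#' cfg <- aaeConfig()
#' cyclicalLearningRate(0, cfg, 8)     # 1e-04 (base)
#' cyclicalLearningRate(32, cfg, 8)    # 5e-03 (first peak)
#' @export
cyclicalLearningRate <- function(step, config, batchesPerEpoch = 8L) {
  stepSize <- config$cycleStepSize
  if (is.null(stepSize)) stepSize <- 4L * batchesPerEpoch
  cycle <- floor(step / (2 * stepSize))            # 0-based cycle index
  pos <- step / stepSize - 2 * cycle               # in [0, 2)
  tri <- 1 - abs(pos - 1)                          # 0 -> 1 -> 0
  amp <- (config$maxLr - config$baseLr) * config$lrGamma^cycle
  config$baseLr + amp * tri
}

#' Train the conditioned adversarial autoencoder on a healthy cohort
#'
#' The normative model is trained on controls only; any non-HC label is an
#' error. The feature pipeline (TIV-relative volumes, robust scaling fitted
#' on this training set) runs internally and the fitted scaler is embedded
#' in the returned model. Each minibatch performs three sequential updates:
#' (1) encoder+decoder minimise the mean squared reconstruction error;
#' (2) the discriminator maximises the log-likelihood of separating
#' standard-normal prior samples from latent codes; (3) the encoder takes a
#' non-saturating generator step to fool the discriminator. All three use
#' Adam with separate moment state and a shared cyclical learning rate.
#' Training is deterministic given the config seed.
#'
#' @param cohort An all-HC \linkS4class{MorphCohort}.
#' @param config An \code{AAEConfig}.
#' @param verbose Print per-epoch losses every 20 epochs.
#' @return A trained \linkS4class{AAEModel} with embedded scaler and a
#'   training log of one row per epoch.
#' @export
trainAAE <- function(cohort, config = aaeConfig(), verbose = FALSE) {
  stopifnot(is(cohort, "MorphCohort"), inherits(config, "AAEConfig"))
  if (!all(subjectGroups(cohort) == "HC"))
    stop("the normative model trains on HC subjects only; found: ",
         paste(setdiff(unique(subjectGroups(cohort)), "HC"), collapse = ", "))
  rel <- relativeVolumes(cohort)
  scaler <- fitScaler(rel)
  X <- applyScaler(rel, scaler)
  C <- conditionMatrix(cohort)
  model <- buildAAE(config, atlas = cohortAtlas(cohort))
  model@scaler <- unclass(scaler)
  fit <- .aaeTrainLoop(X, C, model@encoder, model@decoder,
                       model@discriminator,
                       epochs = config$epochs,
                       batchSize = min(config$batchSize, nrow(X)),
                       baseLr = config$baseLr, maxLr = config$maxLr,
                       lrGamma = config$lrGamma,
                       cycleStepSize = if (is.null(config$cycleStepSize)) -1L
                                       else as.integer(config$cycleStepSize),
                       slope = config$leakySlope,
                       advWeight = config$advWeight,
                       advLrScale = config$advLrScale,
                       discSteps = config$discSteps,
                       latentDim = config$latentDim)
  model@encoder <- fit$encoder
  model@decoder <- fit$decoder
  model@discriminator <- fit$discriminator
  log <- data.frame(epoch = seq_len(config$epochs),
                    recon_loss = fit$recon_loss, disc_loss = fit$disc_loss,
                    gen_loss = fit$gen_loss, lr = fit$lr)
  if (verbose)
    message(sprintf("trained %d epochs: recon %.5f -> %.5f, disc %.4f, gen %.4f",
                    config$epochs, log$recon_loss[1L],
                    log$recon_loss[config$epochs],
                    log$disc_loss[config$epochs],
                    log$gen_loss[config$epochs]))
  model@trainLog <- log
  validObject(model)
  model
}

#' Normalised features and reconstructions for a cohort
#'
#' Applies the trained model's full pipeline — TIV-relative volumes, the
#' embedded training-set scaler, encoder, conditioned decoder — to every
#' subject of a cohort.
#'
#' @param cohort A \linkS4class{MorphCohort} (ages must lie in \[47, 73\],
#'   enforced by the cohort class).
#' @param model A trained \linkS4class{AAEModel}.
#' @return List with matrices \code{x} (normalised inputs) and \code{xhat}
#'   (reconstructions), both subjects x regions, and \code{h} (latent
#'   codes, subjects x latentDim).
#' @export
reconstructCohort <- function(cohort, model) {
  stopifnot(is(model, "AAEModel"))
  if (!length(model@scaler))
    stop("model has no embedded scaler; train it first")
  if (!identical(cohortAtlas(cohort)$name, model@atlas$name))
    stop("cohort and model atlas disagree")
  scaler <- structure(model@scaler, class = "ScalerParams")
  x <- applyScaler(relativeVolumes(cohort), scaler)
  h <- aaeEncode(model, x)
  xhat <- aaeDecode(model, h, conditionMatrix(cohort))
  dimnames(xhat) <- dimnames(x)
  list(x = x, xhat = xhat, h = h)
}

#' Save / load an AAE model artefact
#'
#' The artefact is a single RDS file bundling config, scaler, atlas,
#' weights and training log, plus a sidecar \code{<path>.md5} checksum.
#' Loading verifies the checksum when the sidecar is present and refuses a
#' tampered artefact. The round trip is bit-exact.
#'
#' @param model An \linkS4class{AAEModel}.
#' @param path Destination file path.
#' @return \code{saveAAEModel}: invisibly, \code{path};
#'   \code{readAAEModel}: the model.
#' @export
saveAAEModel <- function(model, path) {
  stopifnot(is(model, "AAEModel"))
  saveRDS(model, path, version = 3L)
  writeLines(unname(tools::md5sum(path)), paste0(path, ".md5"))
  invisible(path)
}

#' @rdname saveAAEModel
#' @export
readAAEModel <- function(path) {
  sidecar <- paste0(path, ".md5")
  if (file.exists(sidecar)) {
    want <- readLines(sidecar, warn = FALSE)[1L]
    have <- unname(tools::md5sum(path))
    if (!identical(want, have))
      stop("model artefact checksum mismatch: '", path,
           "' does not match its .md5 sidecar (tampered or corrupted file)")
  }
  model <- readRDS(path)
  if (!is(model, "AAEModel")) stop("'", path, "' is not an AAEModel artefact")
  model
}

#' Check the trained latent distribution against the prior
#'
#' Two diagnostics of adversarial prior matching: (i) per-dimension moments
#' of the encoded training data, to compare with the standard-normal prior;
#' (ii) a freshly trained discriminator-style probe (same architecture as
#' the model's discriminator) fitted on half of the prior/encoded samples,
#' with its AUC measured on the held-out half — near 0.5 means the encoded
#' distribution is indistinguishable from the prior.
#'
#' @param model A trained \linkS4class{AAEModel}.
#' @param cohort Cohort whose encoded codes are probed.
#' @param seed Seed for prior sampling, the probe split and its training.
#' @param probeEpochs Training epochs for the probe.
#' @return List: \code{latentMean}, \code{latentSd} (per-dimension),
#'   \code{probeAuc}.
#' @export
latentPriorCheck <- function(model, cohort, seed = 1L, probeEpochs = 60L) {
  h <- reconstructCohort(cohort, model)$h
  set.seed(seed)
  n <- nrow(h)
  d <- ncol(h)
  prior <- matrix(rnorm(n * d), n, d)
  z <- rbind(prior, h)
  y <- c(rep(1, n), rep(0, n))
  test <- sample.int(2L * n, n)           # half train, half held out
  slope <- model@config$leakySlope
  net <- mlpInit(c(d, model@config$discriminatorHidden, 1L))
  opt <- adamInit(net)
  tr <- setdiff(seq_len(2L * n), test)
  bs <- min(128L, length(tr))
  for (ep in seq_len(probeEpochs)) {
    perm <- sample(tr)
    for (bi in seq_len(floor(length(tr) / bs))) {
      idx <- perm[((bi - 1L) * bs + 1L):(bi * bs)]
      f <- mlpForward(net, z[idx, , drop = FALSE], slope)
      dA <- matrix((sigmoid(f$out) - y[idx]) / length(idx), ncol = 1L)
      b <- mlpBackward(net, f, dA, slope, needInputGrad = FALSE)
      up <- adamStep(net, b, opt, 1e-3); net <- up$net; opt <- up$state
    }
  }
  scores <- as.numeric(mlpForward(net, z[test, , drop = FALSE], slope)$out)
  auc <- aucFromScores(scores[y[test] == 1], scores[y[test] == 0])
  list(latentMean = colMeans(h), latentSd = apply(h, 2L, stats::sd),
       probeAuc = auc)
}
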
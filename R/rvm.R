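#' Fit a linear-kernel relevance vector machine classifier
#'
#' Sparse Bayesian classification of the form popularised by Tipping
#' (2001): an SVM-like linear-kernel model
#' \eqn{f(x) = \sum_n w_n \, k(x, x_n) + w_0} with an independent Gaussian
#' prior \eqn{w_n \sim N(0, \alpha_n^{-1})} on every weight. Fitting
#' alternates a Laplace approximation of the posterior (Newton/IRLS on the
#' penalised Bernoulli log-likelihood) with evidence-based updates
#' \eqn{\alpha_n \leftarrow \gamma_n / w_n^2}; weights whose precision
#' diverges are pruned, leaving a sparse set of relevance vectors. No
#' margin/cost parameter is required. The fit is deterministic.
#'
#' @param features Numeric matrix (subjects x features), already scaled the
#'   same way as the normative path (TIV-relative, robust-scaled).
#' @param labels Binary vector (0/1 or logical; 1 = patient class), both
#'   classes present with >= 2 samples each.
#' @param maxIter Maximum outer evidence-update iterations.
#' @param tol Convergence tolerance on the maximum change of
#'   \eqn{\log\alpha}.
#' @param pruneThreshold Weights whose precision \eqn{\alpha} exceeds this
#'   value are pruned from the model (the convention of standard sparse
#'   Bayesian learning implementations).
#' @return A list of class \code{"RVMModel"}: \code{relevanceIndex}
#'   (indices into the training set; 0 denotes the bias), \code{weights},
#'   \code{relevanceVectors}, \code{alpha}, \code{iterations},
#'   \code{converged}.
#' @references Tipping, M. E. (2001). Sparse Bayesian learning and the
#'   relevance vector machine. JMLR 1, 211-244.
#' @export
fitRVM <- function(features, labels, maxIter = 100L, tol = 1e-3,
                   pruneThreshold = 1e9) {
  X <- as.matrix(features)
  t <- as.numeric(labels)
  if (!all(t %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (length(unique(t)) < 2L)
    stop("both classes must be present in the training set")
  if (min(table(t)) < 2L) stop("each class needs >= 2 training samples")
  n <- nrow(X)
  ## design matrix: bias + linear kernel against every training point
  Phi <- cbind(1, tcrossprod(X))
  M <- ncol(Phi)
  active <- seq_len(M)
  alpha <- rep(1 / n^2, M)
  w <- numeric(M)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Pa <- Phi[, active, drop = FALSE]
    wa <- w[active]
    ## Laplace approximation: Newton steps on penalised log-likelihood
    for (inner in seq_len(50L)) {
      y <- sigmoid(as.numeric(Pa %*% wa))
      g <- crossprod(Pa, t - y) - alpha[active] * wa
      Bv <- pmax(y * (1 - y), 1e-10)
      H <- crossprod(Pa, Pa * Bv)
      diag(H) <- diag(H) + alpha[active]
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      ## backtracking on the penalised objective
      obj <- function(wv) {
        f <- as.numeric(Pa %*% wv)
        sum(t * logSigmoid(f) + (1 - t) * logSigmoid(-f)) -
          0.5 * sum(alpha[active] * wv^2)
      }
      o0 <- obj(wa)
      lam <- 1
      repeat {
        wNew <- wa + lam * step
        if (obj(wNew) >= o0 || lam < 1e-8) break
        lam <- lam / 2
      }
      moved <- max(abs(wNew - wa))
      wa <- wNew
      if (moved < 1e-8) break
    }
    ## posterior covariance at the mode; evidence update of alpha
    y <- sigmoid(as.numeric(Pa %*% wa))
    Bv <- pmax(y * (1 - y), 1e-10)
    H <- crossprod(Pa, Pa * Bv)
    diag(H) <- diag(H) + alpha[active]
    Sigma <- tryCatch(chol2inv(chol(H)), error = function(e) solve(H))
    gamma <- pmax(1 - alpha[active] * diag(Sigma), 1e-12)
    alphaNew <- gamma / pmax(wa^2, .Machine$double.xmin)
    alphaNew <- pmin(alphaNew, 1e12)
    delta <- max(abs(log(alphaNew) - log(alpha[active])))
    alpha[active] <- alphaNew
    w[active] <- wa
    ## prune weights whose precision has diverged
    keep <- alpha[active] <= pruneThreshold
    if (!all(keep)) {
      w[active[!keep]] <- 0
      active <- active[keep]
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  relIdx <- active - 1L            # 0 = bias term
  structure(list(relevanceIndex = relIdx,
                 weights = w[active],
                 relevanceVectors = X[relIdx[relIdx > 0L], , drop = FALSE],
                 alpha = alpha[active],
                 iterations = it, converged = converged,
                 nTrain = n, nFeatures = ncol(X)),
            class = "RVMModel")
}

#' @export
print.RVMModel <- function(x, ...) {
  cat(sprintf("RVM (linear kernel): %d relevance vectors of %d training points%s\n",
              sum(x$relevanceIndex > 0L), x$nTrain,
              if (0L %in% x$relevanceIndex) " + bias" else ""))
  invisible(x)
}

#' Predict patient-class probabilities from a fitted RVM
#'
#' @param model An \code{"RVMModel"} from [fitRVM()].
#' @param features Numeric matrix (subjects x features), same width and
#'   scaling as the training features.
#' @return Vector of probabilities in (0, 1) of belonging to the patient
#'   class.
#' @export
predictRVM <- function(model, features) {
  stopifnot(inherits(model, "RVMModel"))
  X <- as.matrix(features)
  if (ncol(X) != model$nFeatures)
    stop("feature width mismatch: model expects ", model$nFeatures)
  f <- numeric(nrow(X))
  hasBias <- 0L %in% model$relevanceIndex
  wv <- model$weights
  if (hasBias) {
    f <- f + wv[model$relevanceIndex == 0L]
    wv <- wv[model$relevanceIndex > 0L]
  }
  if (nrow(model$relevanceVectors))
    f <- f + as.numeric(tcrossprod(X, model$relevanceVectors) %*% wv)
  sigmoid(f)
}

#' 0.632+ blending weight from resubstitution and out-of-bag AUC
#'
#' The relative overfitting rate, adapted to AUC with 0.5 as the
#' no-information rate:
#' \deqn{R = \frac{AUC_{resub} - AUC_{oob}}{AUC_{resub} - 0.5}, \qquad
#'   \omega = \frac{0.632}{1 - 0.368 R},}
#' with \eqn{R} clipped to \[0, 1\] and \eqn{\omega} capped at 1, so
#' \eqn{\omega \in [0.632, 1]}: 0.632 under no overfitting, 1 under
#' complete overfitting.
#'
#' @param aucResub Resubstitution (training-set) AUC.
#' @param aucOob Out-of-bag (test-set) AUC.
#' @return The weight \eqn{\omega}.
#' @export
omegaWeight <- function(aucResub, aucOob) {
  if (any(c(aucResub, aucOob) < 0) || any(c(aucResub, aucOob) > 1))
    stop("AUCs must lie in [0, 1]")
  denom <- aucResub - 0.5
  R <- ifelse(denom <= 0, 0, (aucResub - aucOob) / denom)
  R <- pmin(pmax(R, 0), 1)
  pmin(0.632 / (1 - 0.368 * R), 1)
}

#' 0.632+ bootstrap AUC of the RVM classifier
#'
#' Within-cohort classifier benchmark for one binary contrast (HC vs one
#' patient group): in each of \code{b} iterations the pooled HC+patient
#' subjects are resampled with replacement to the pool's size, subjects
#' never drawn form the out-of-bag set, the robust scaler and the RVM are
#' fitted on the bootstrap sample, and the resubstitution and out-of-bag
#' AUCs are blended per iteration with the [omegaWeight()]. Iterations
#' whose out-of-bag set lacks one class are redrawn so the iteration count
#' stays fixed. The aggregate is the mean of the blended values; the CI is
#' the percentile interval of the blended values.
#'
#' @param cohort A \linkS4class{MorphCohort} containing both groups.
#' @param contrast Character of length 2: \code{c("HC", <patient group>)}.
#' @param b Number of bootstrap iterations.
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @param level Confidence level.
#' @param keepModels Keep each iteration's fitted RVM and scaler (needed
#'   for [crossCohortGeneralization()]).
#' @return A list of class \code{"Bootstrap632Result"}: \code{poolSize}
#'   (each bootstrap draw's size = pooled HC+patient count); per-iteration
#'   \code{aucResub}, \code{aucOob}, \code{omega}, \code{blended};
#'   \code{aucBootstrap} (the aggregate), \code{ci}, \code{redraws}, and
#'   optionally \code{models}.
#' @export
bootstrap632Auc <- function(cohort, contrast, b = 50L, seed = 1L,
                            level = 0.95, keepModels = FALSE) {
  stopifnot(length(contrast) == 2L, "HC" %in% contrast)
  patient <- setdiff(contrast, "HC")
  pool <- subsetGroups(cohort, contrast)
  grp <- subjectGroups(pool)
  if (min(table(grp)) < 2L) stop("each contrast group needs >= 2 subjects")
  lab <- as.numeric(grp == patient)
  rel <- relativeVolumes(pool)
  n <- nrow(rel)
  aucResub <- aucOob <- omega <- numeric(b)
  models <- if (keepModels) vector("list", b) else NULL
  redraws <- 0L
  for (i in seq_len(b)) {
    set.seed(deriveSeed(seed, "rvm632", i))
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (length(unique(lab[oob])) == 2L) break
      redraws <- redraws + 1L
    }
    scaler <- fitScaler(rel[idx, , drop = FALSE])
    Xtr <- applyScaler(rel[idx, , drop = FALSE], scaler)
    Xte <- applyScaler(rel[oob, , drop = FALSE], scaler)
    fit <- fitRVM(Xtr, lab[idx])
    pTr <- predictRVM(fit, Xtr)
    pTe <- predictRVM(fit, Xte)
    aucResub[i] <- aucFromScores(pTr[lab[idx] == 1], pTr[lab[idx] == 0])
    aucOob[i] <- aucFromScores(pTe[lab[oob] == 1], pTe[lab[oob] == 0])
    omega[i] <- omegaWeight(aucResub[i], aucOob[i])
    if (keepModels) models[[i]] <- list(fit = fit, scaler = scaler)
  }
  blended <- omega * aucOob + (1 - omega) * aucResub
  structure(list(b = b, contrast = contrast, poolSize = n,
                 aucResub = aucResub,
                 aucOob = aucOob, omega = omega, blended = blended,
                 aucBootstrap = mean(blended),
                 ci = percentileCI(blended, level), redraws = redraws,
                 models = models),
            class = "Bootstrap632Result")
}

#' @export
print.Bootstrap632Result <- function(x, ...) {
  cat(sprintf("0.632+ bootstrap AUC (HC vs %s, b = %d): %.3f [%.3f, %.3f]\n",
              setdiff(x$contrast, "HC"), x$b, x$aucBootstrap, x$ci$lower,
              x$ci$upper))
  invisible(x)
}

#' Cross-cohort generalization of per-iteration classifiers
#'
#' Every per-iteration RVM from a within-cohort [bootstrap632Auc()] run
#' (fitted with \code{keepModels = TRUE}) scores the HC + target-group
#' subjects of each external test cohort, normalised with the TRAINING
#' iteration's scaler. Cells report the mean AUC over iterations with its
#' percentile CI — the generalization-matrix layout of the classifier
#' comparison.
#'
#' @param result A \code{Bootstrap632Result} with kept models.
#' @param testCohorts List of \linkS4class{MorphCohort}s sharing the atlas.
#' @param targetGroup Patient group label in the test cohorts; defaults to
#'   the trained contrast's patient group.
#' @param level Confidence level.
#' @return A list of class \code{"GeneralizationResult"}: \code{aucs}
#'   (iterations x test cohorts) and \code{summary} (data.frame: test
#'   cohort, auc, lower, upper).
#' @export
crossCohortGeneralization <- function(result, testCohorts,
                                      targetGroup = setdiff(result$contrast,
                                                            "HC"),
                                      level = 0.95) {
  stopifnot(inherits(result, "Bootstrap632Result"))
  if (is.null(result$models))
    stop("run bootstrap632Auc with keepModels = TRUE first")
  if (is(testCohorts, "MorphCohort")) testCohorts <- list(testCohorts)
  names(testCohorts) <- vapply(testCohorts, cohortName, character(1))
  aucs <- matrix(NA_real_, result$b, length(testCohorts),
                 dimnames = list(NULL, names(testCohorts)))
  for (cn in names(testCohorts)) {
    te <- subsetGroups(testCohorts[[cn]], c("HC", targetGroup))
    lab <- as.numeric(subjectGroups(te) == targetGroup)
    rel <- relativeVolumes(te)
    for (i in seq_len(result$b)) {
      m <- result$models[[i]]
      p <- predictRVM(m$fit, applyScaler(rel, m$scaler))
      aucs[i, cn] <- aucFromScores(p[lab == 1], p[lab == 0])
    }
  }
  summ <- do.call(rbind, lapply(colnames(aucs), function(cn) {
    ci <- percentileCI(aucs[, cn], level)
    data.frame(test_cohort = cn, auc = ci$point, lower = ci$lower,
               upper = ci$upper, stringsAsFactors = FALSE)
  }))
  structure(list(aucs = aucs, summary = summ, targetGroup = targetGroup),
            class = "GeneralizationResult")
}

#' @export
print.GeneralizationResult <- function(x, ...) {
  cat(sprintf("Cross-cohort generalization (target group %s):\n",
              x$targetGroup))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired CI on the difference of two bootstrap AUC series
#'
#' Pairs the two schemes iteration by iteration, takes the per-iteration
#' differences \code{a - b}, and reports their percentile CI; the
#' difference is significant when the CI excludes zero. Used to compare
#' classifier AUCs against the normative deviation-score AUCs.
#'
#' @param aucSamplesA,aucSamplesB Equal-length per-iteration AUC vectors.
#' @param level Confidence level.
#' @return A list: \code{ci} (a \code{PercentileCI} of the differences) and
#'   \code{significant}.
#' @export
aucDifferenceCI <- function(aucSamplesA, aucSamplesB, level = 0.95) {
  if (length(aucSamplesA) != length(aucSamplesB))
    stop("the two AUC series must have equal iteration counts")
  d <- aucSamplesA - aucSamplesB
  ci <- percentileCI(d, level)
  list(ci = ci, significant = ci$lower > 0 || ci$upper < 0)
}
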
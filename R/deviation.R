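#' Observed deviation of a subject
#'
#' The normative deviation score: the mean squared error between a
#' subject's normalised regional features and their autoencoder
#' reconstruction,
#' \deqn{d = \frac{1}{p} \sum_{i=1}^{p} (x_i - \hat{x}_i)^2,}
#' with \eqn{p} the number of regions (101 in the default atlas).
#'
#' @param x Normalised feature vector, or matrix (subjects x regions).
#' @param xhat Reconstruction of the same shape.
#' @return Non-negative scalar, or vector of one score per subject.
#' @export
observedDeviation <- function(x, xhat) {
  if (is.matrix(x)) {
    if (!all(dim(x) == dim(xhat))) stop("x and xhat shapes differ")
    rowMeans((x - xhat)^2)
  } else {
    if (length(x) != length(xhat)) stop("x and xhat lengths differ")
    mean((x - xhat)^2)
  }
}

#' Per-region deviations
#'
#' Squared per-region reconstruction errors \eqn{(x_i - \hat{x}_i)^2}; by
#' construction their mean is exactly the observed deviation. Set
#' \code{signed = TRUE} for the signed residuals \eqn{x_i - \hat{x}_i}
#' instead (direction of deviation: positive = larger than reconstructed).
#'
#' @param x Normalised feature vector or matrix (subjects x regions).
#' @param xhat Reconstruction, same shape.
#' @param signed Return signed residuals instead of squared errors.
#' @return Same shape as \code{x}.
#' @export
regionDeviations <- function(x, xhat, signed = FALSE) {
  if (is.matrix(x) && !all(dim(x) == dim(xhat)))
    stop("x and xhat shapes differ")
  if (!is.matrix(x) && length(x) != length(xhat))
    stop("x and xhat lengths differ")
  d <- x - xhat
  if (signed) d else d^2
}

#' Score every subject of a cohort against a trained normative model
#'
#' @param cohort A \linkS4class{MorphCohort}.
#' @param model A trained \linkS4class{AAEModel}.
#' @return A data.frame (subject_id, group, observed_deviation) with the
#'   per-region squared-error matrix attached as attribute
#'   \code{"regionDeviations"}.
#' @export
scoreDeviations <- function(cohort, model) {
  r <- reconstructCohort(cohort, model)
  dev <- regionDeviations(r$x, r$xhat)
  out <- data.frame(subject_id = subjectIDs(cohort),
                    group = subjectGroups(cohort),
                    observed_deviation = rowMeans(dev),
                    stringsAsFactors = FALSE)
  attr(out, "regionDeviations") <- dev
  out
}

# shared pair statistic: U = #{a_i > b_j} + 0.5 #{a_i = b_j}, via midranks
pairU <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b), ties.method = "average")
  sum(r[seq_len(n)]) - n * (n + 1) / 2
}

#' Area under the ROC curve from deviation scores
#'
#' The probability that a randomly chosen patient scores above a randomly
#' chosen control, ties counted one half — the Mann-Whitney statistic
#' divided by \eqn{nm}, identical to the trapezoidal ROC area.
#'
#' @param pos Scores of the patient (positive) group.
#' @param neg Scores of the control (negative) group.
#' @return AUC in \[0, 1\].
#' @export
aucFromScores <- function(pos, neg) {
  if (!length(pos) || !length(neg)) stop("both groups must be non-empty")
  pairU(pos, neg) / (length(pos) * length(neg))
}

#' Cliff's delta effect size
#'
#' Nonparametric effect size
#' \eqn{\delta = P(a > b) - P(a < b)} over all pairs; ties contribute zero.
#' Related to the AUC by \eqn{AUC = (\delta + 1)/2}, an identity the two
#' implementations satisfy by sharing one pair-counting core.
#'
#' @param a,b Non-empty numeric samples.
#' @return \eqn{\delta \in [-1, 1]}.
#' @export
cliffsDelta <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  2 * aucFromScores(a, b) - 1
}

#' Percentile bootstrap confidence interval
#'
#' Empirical (2.5, 97.5) percentiles (for the default 95\% level) of a set
#' of bootstrap replicates, with linear interpolation between order
#' statistics (R quantile type 7); the point estimate is the mean.
#'
#' @param samples Numeric vector of bootstrap replicates (length >= 2).
#' @param level Confidence level in (0, 1).
#' @return A list of class \code{"PercentileCI"}: \code{point},
#'   \code{lower}, \code{upper}, \code{level}.
#' @export
percentileCI <- function(samples, level = 0.95) {
  if (length(samples) < 2L) stop("need >= 2 bootstrap replicates")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  alpha <- (1 - level) / 2
  q <- quantile(samples, probs = c(alpha, 1 - alpha), names = FALSE,
                type = 7L)
  structure(list(point = mean(samples), lower = q[1L], upper = q[2L],
                 level = level),
            class = "PercentileCI")
}

#' @export
print.PercentileCI <- function(x, ...) {
  cat(sprintf("%.4g [%.4g, %.4g] (%d%% percentile CI)\n", x$point, x$lower,
              x$upper, round(100 * x$level)))
  invisible(x)
}

ciExcludesZero <- function(samples, level = 0.95) {
  ci <- percentileCI(samples, level)
  ci$lower > 0 || ci$upper < 0
}

# deterministic per-iteration seeds derived from one master seed, so any
# single bootstrap iteration can be replayed in isolation
deriveSeed <- function(master, stage, index) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 2654435769 + h * 97 + index * 1013904223) %%
               2147483647)
}

#' Bootstrap evaluation of the normative model
#'
#' The resampling scheme used for all headline normative results: in each
#' of \code{B} iterations a bootstrap training set is drawn with
#' replacement from the healthy reference cohort, the robust scaler is
#' re-fitted on it, a fresh AAE is trained on it, and every subject of
#' every clinical cohort is scored. Per iteration the function records the
#' per-group mean deviation, all pairwise group mean differences, the AUC
#' of each patient-group-vs-HC contrast, and the per-region Cliff's delta
#' of each contrast. Percentile CIs aggregate over iterations; a difference
#' or effect is flagged significant when its 95\% CI excludes zero.
#'
#' @param reference All-HC \linkS4class{MorphCohort} used for training.
#' @param clinical A \linkS4class{MorphCohort} or list of them; each must
#'   contain an HC group.
#' @param config \code{AAEConfig} used for every iteration's model.
#' @param B Number of bootstrap iterations (>= 1). The reference analysis
#'   uses 1,000; the desk-scale default is 20.
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @param sizeOffset Bootstrap training sets have \code{n_ref - sizeOffset}
#'   subjects; 0 is the standard bootstrap (the reference analysis drew
#'   11,032 of 11,034, i.e. offset 2).
#' @param level Confidence level for all CIs.
#' @param verbose Progress messages per iteration.
#' @return An object of class \code{"NormativeBootstrap"} (list) with
#'   per-iteration arrays and summary tables; see
#'   [deviationSummary()], [aucSummary()], [regionEffectSummary()].
#' @export
bootstrapNormativeEvaluation <- function(reference, clinical,
                                         config = aaeConfig(), B = 20L,
                                         seed = 1L, sizeOffset = 0L,
                                         level = 0.95, verbose = FALSE) {
  if (is(clinical, "MorphCohort")) clinical <- list(clinical)
  if (B < 1L) stop("B must be >= 1")
  if (!all(subjectGroups(reference) == "HC"))
    stop("reference cohort must contain HC subjects only")
  names(clinical) <- vapply(clinical, cohortName, character(1))
  for (co in clinical)
    if (!"HC" %in% subjectGroups(co))
      stop("clinical cohort '", cohortName(co), "' lacks an HC group")
  nref <- ncol(reference)
  ntrain <- nref - as.integer(sizeOffset)
  if (ntrain < 4L) stop("bootstrap training size too small")
  groupsOf <- lapply(clinical, function(co) sort(unique(subjectGroups(co))))
  contrastsOf <- lapply(groupsOf, function(g) setdiff(g, "HC"))
  p <- nrow(reference)
  regions <- cohortAtlas(reference)$name
  groupMeans <- list(); aucs <- list(); deltas <- list(); diffs <- list()
  for (cn in names(clinical)) {
    groupMeans[[cn]] <- matrix(NA_real_, B, length(groupsOf[[cn]]),
                               dimnames = list(NULL, groupsOf[[cn]]))
    prs <- utils::combn(groupsOf[[cn]], 2L)
    diffs[[cn]] <- matrix(NA_real_, B, ncol(prs),
                          dimnames = list(NULL, paste(prs[2L, ], prs[1L, ],
                                                      sep = "-")))
    aucs[[cn]] <- matrix(NA_real_, B, length(contrastsOf[[cn]]),
                         dimnames = list(NULL, contrastsOf[[cn]]))
    deltas[[cn]] <- array(NA_real_, c(B, p, length(contrastsOf[[cn]])),
                          dimnames = list(NULL, regions, contrastsOf[[cn]]))
  }
  for (b in seq_len(B)) {
    iterSeed <- deriveSeed(seed, "normative", b)
    set.seed(iterSeed)
    idx <- sample.int(nref, ntrain, replace = TRUE)
    cfg_b <- config
    cfg_b$seed <- deriveSeed(iterSeed, "train", b)
    model <- trainAAE(resampleCohort(reference, idx), cfg_b)
    for (cn in names(clinical)) {
      sc <- scoreDeviations(clinical[[cn]], model)
      dev <- sc$observed_deviation
      reg <- attr(sc, "regionDeviations")
      grp <- sc$group
      gm <- tapply(dev, grp, mean)
      groupMeans[[cn]][b, names(gm)] <- gm
      prs <- utils::combn(groupsOf[[cn]], 2L)
      diffs[[cn]][b, ] <- gm[prs[2L, ]] - gm[prs[1L, ]]
      hcDev <- dev[grp == "HC"]
      hcReg <- reg[grp == "HC", , drop = FALSE]
      for (g in contrastsOf[[cn]]) {
        aucs[[cn]][b, g] <- aucFromScores(dev[grp == g], hcDev)
        gReg <- reg[grp == g, , drop = FALSE]
        deltas[[cn]][b, , g] <- vapply(seq_len(p), function(r)
          cliffsDelta(gReg[, r], hcReg[, r]), numeric(1))
      }
    }
    if (verbose)
      message(sprintf("bootstrap iteration %d/%d done (seed %d)", b, B,
                      iterSeed))
  }
  structure(list(B = B, level = level, seed = seed,
                 groups = groupsOf, contrasts = contrastsOf,
                 groupMeans = groupMeans, meanDiffs = diffs, aucs = aucs,
                 regionDeltas = deltas, regions = regions),
            class = "NormativeBootstrap")
}

#' @export
print.NormativeBootstrap <- function(x, ...) {
  cat(sprintf("NormativeBootstrap: %d iterations over %d clinical cohort(s)\n",
              x$B, length(x$groupMeans)))
  print(deviationSummary(x), row.names = FALSE)
  invisible(x)
}

#' Group mean deviations with percentile CIs
#'
#' One row per (cohort, group): the bootstrap mean of the group's mean
#' observed deviation with its percentile CI — the tabular analogue of the
#' per-group deviation figure.
#'
#' @param x A \code{NormativeBootstrap}.
#' @return data.frame: cohort, group, mean_deviation, lower, upper.
#' @export
deviationSummary <- function(x) {
  do.call(rbind, lapply(names(x$groupMeans), function(cn) {
    m <- x$groupMeans[[cn]]
    do.call(rbind, lapply(colnames(m), function(g) {
      ci <- percentileCI(m[, g], x$level)
      data.frame(cohort = cn, group = g, mean_deviation = ci$point,
                 lower = ci$lower, upper = ci$upper,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Pairwise group mean-difference CIs
#'
#' @param x A \code{NormativeBootstrap}.
#' @return data.frame: cohort, contrast (\code{"B-A"} = mean(B) - mean(A)),
#'   difference, lower, upper, significant (CI excludes zero).
#' @export
groupDifferenceSummary <- function(x) {
  do.call(rbind, lapply(names(x$meanDiffs), function(cn) {
    m <- x$meanDiffs[[cn]]
    do.call(rbind, lapply(colnames(m), function(ct) {
      ci <- percentileCI(m[, ct], x$level)
      data.frame(cohort = cn, contrast = ct, difference = ci$point,
                 lower = ci$lower, upper = ci$upper,
                 significant = ci$lower > 0 || ci$upper < 0,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Discriminative performance of the deviation score
#'
#' Mean AUC (patient group vs HC, deviation score as the decision value)
#' with percentile CI per contrast.
#'
#' @param x A \code{NormativeBootstrap}.
#' @return data.frame: cohort, group, auc, lower, upper.
#' @export
aucSummary <- function(x) {
  do.call(rbind, lapply(names(x$aucs), function(cn) {
    m <- x$aucs[[cn]]
    do.call(rbind, lapply(colnames(m), function(g) {
      ci <- percentileCI(m[, g], x$level)
      data.frame(cohort = cn, group = g, auc = ci$point, lower = ci$lower,
                 upper = ci$upper, stringsAsFactors = FALSE)
    }))
  }))
}

#' Per-region Cliff's delta effect sizes
#'
#' Mean Cliff's delta of each region's deviation (patient group vs HC)
#' across bootstrap iterations, with percentile CI and significance flag
#' (CI excludes zero) — the tabular analogue of the region-deviation
#' figure.
#'
#' @param x A \code{NormativeBootstrap}.
#' @param cohort Cohort name (default: first clinical cohort).
#' @return data.frame: cohort, region, contrast, delta, lower, upper,
#'   significant; ordered by |delta| within contrast.
#' @export
regionEffectSummary <- function(x, cohort = names(x$regionDeltas)[1L]) {
  arr <- x$regionDeltas[[cohort]]
  out <- do.call(rbind, lapply(dimnames(arr)[[3L]], function(g) {
    do.call(rbind, lapply(seq_along(x$regions), function(r) {
      ci <- percentileCI(arr[, r, g], x$level)
      data.frame(cohort = cohort, region = x$regions[r], contrast = g,
                 delta = ci$point, lower = ci$lower, upper = ci$upper,
                 significant = ci$lower > 0 || ci$upper < 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  out[order(out$contrast, -abs(out$delta)), ]
}
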
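#' TIV-relative volumes
#'
#' Divides each subject's raw regional volumes by that subject's total
#' intracranial volume, removing head-size differences. First stage of the
#' normative feature pipeline.
#'
#' @param cohort A \linkS4class{MorphCohort}.
#' @return Numeric matrix, subjects x regions, of relative volumes.
#' @export
relativeVolumes <- function(cohort) {
  tiv <- subjectTIV(cohort)
  if (any(tiv <= 0)) stop("tiv must be > 0 for every subject")
  volumeMatrix(cohort) / tiv
}

#' Fit the outlier-robust scaler on a training set
#'
#' Computes, independently for each region, the median and interquartile
#' range of the relative volumes over the training subjects. Quantiles use
#' linear interpolation between order statistics (R type 7). The fitted
#' statistics are frozen and re-applied unchanged to clinical data — the
#' scaler is part of the trained model.
#'
#' @param x Numeric matrix of relative volumes (subjects x regions), at
#'   least 4 rows.
#' @return A list of class \code{"ScalerParams"}: \code{center} (medians)
#'   and \code{scale} (IQRs), both named by region.
#' @export
fitScaler <- function(x) {
  if (!is.matrix(x) || nrow(x) < 4L)
    stop("scaler fitting needs a matrix with >= 4 training subjects")
  center <- apply(x, 2L, median)
  q <- apply(x, 2L, quantile, probs = c(0.25, 0.75), names = FALSE, type = 7L)
  scale <- q[2L, ] - q[1L, ]
  zero <- which(scale <= 0)
  if (length(zero))
    stop("zero interquartile range (constant region): ",
         paste(head(colnames(x)[zero], 5L), collapse = ", "))
  structure(list(center = setNames(center, colnames(x)),
                 scale = setNames(scale, colnames(x))),
            class = "ScalerParams")
}

#' Apply a fitted robust scaler
#'
#' \eqn{z_r = (x_r - median_r) / IQR_r}, per region. Accepts a vector (one
#' subject) or a matrix (subjects x regions).
#'
#' @param x Numeric vector or matrix of relative volumes.
#' @param params A \code{ScalerParams} from [fitScaler()].
#' @return Normalised features, same shape as \code{x}.
#' @export
applyScaler <- function(x, params) {
  if (!inherits(params, "ScalerParams"))
    stop("params must be a fitted ScalerParams object")
  if (is.matrix(x)) {
    if (ncol(x) != length(params$center)) stop("feature width mismatch")
    sweep(sweep(x, 2L, params$center), 2L, params$scale, "/")
  } else {
    if (length(x) != length(params$center)) stop("feature length mismatch")
    (x - params$center) / params$scale
  }
}

#' Invert a fitted robust scaler
#'
#' @param z Normalised features (vector or matrix).
#' @param params A \code{ScalerParams}.
#' @return Relative volumes on the original scale.
#' @export
invertScaler <- function(z, params) {
  if (is.matrix(z)) sweep(sweep(z, 2L, params$scale, "*"), 2L, params$center, "+")
  else z * params$scale + params$center
}

#' One-hot encode age
#'
#' Age conditioning vector with 27 positions, one per year of the 47-73
#' range in ascending order: position \code{age - 46} is 1, all others 0.
#'
#' @param age Integer vector of ages in \[47, 73\].
#' @return Binary matrix, \code{length(age)} x 27.
#' @export
oneHotAge <- function(age) {
  if (any(age != round(age))) stop("age must be integer years")
  if (any(age < AGE_MIN | age > AGE_MAX))
    stop(sprintf("age outside [%d, %d]", AGE_MIN, AGE_MAX))
  n_levels <- AGE_MAX - AGE_MIN + 1L
  out <- matrix(0, length(age), n_levels,
                dimnames = list(NULL, paste0("age", AGE_MIN:AGE_MAX)))
  out[cbind(seq_along(age), as.integer(age) - AGE_MIN + 1L)] <- 1
  out
}

#' One-hot encode sex
#'
#' Two positions in the order (male, female).
#'
#' @param sex Character vector with values \code{"male"} or \code{"female"}.
#' @return Binary matrix, \code{length(sex)} x 2.
#' @export
oneHotSex <- function(sex) {
  if (any(!sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  out <- matrix(0, length(sex), 2L, dimnames = list(NULL, c("male", "female")))
  out[cbind(seq_along(sex), ifelse(sex == "male", 1L, 2L))] <- 1
  out
}

#' Demographic condition matrix for a cohort
#'
#' Concatenation of the age and sex one-hot encodings (29 columns) fed to
#' the decoder alongside the latent code.
#'
#' @param cohort A \linkS4class{MorphCohort}.
#' @return Binary matrix, subjects x 29.
#' @export
conditionMatrix <- function(cohort) {
  cbind(oneHotAge(subjectAges(cohort)), oneHotSex(subjectSex(cohort)))
}
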
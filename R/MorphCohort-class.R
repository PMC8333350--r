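#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom aov chisq.test
#'   plogis qnorm setNames
#' @importFrom utils read.csv write.csv head
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
NULL

# Age window of the normative model: the healthy reference sample spans
# 47-73 years and age is one-hot encoded over that integer range, so any
# record entering training or scoring must fall inside it.
AGE_MIN <- 47L
AGE_MAX <- 73L

#' MorphCohort: a cohort of regional brain volumes
#'
#' S4 container for one morphometry cohort, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"volumes"}
#' holds raw regional volumes in cubic millimetres with regions (101 atlas
#' entries) as rows and subjects as columns; \code{colData} carries the
#' per-subject demographics (\code{subject_id}, \code{age} in integer years,
#' \code{sex} coded \code{"male"}/\code{"female"}, diagnostic \code{group},
#' and \code{tiv}, the estimated total intracranial volume); \code{rowData}
#' carries the atlas (region \code{kind}, hemisphere).
#'
#' Validity enforces the contract every record must satisfy before it can
#' enter the normative model: exactly 101 regions, integer ages in
#' \[47, 73\], positive TIV, non-negative finite volumes, no missing values.
#'
#' @aliases MorphCohort
#' @export
setClass("MorphCohort", contains = "SummarizedExperiment")

setValidity("MorphCohort", function(object) {
  msg <- character()
  v <- SummarizedExperiment::assays(object)
  if (!"volumes" %in% names(v))
    return("assay 'volumes' is required")
  vol <- v[["volumes"]]
  if (nrow(vol) != 101L)
    msg <- c(msg, sprintf("expected 101 atlas regions, found %d", nrow(vol)))
  cd <- colData(object)
  need <- c("subject_id", "age", "sex", "group", "tiv")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("missing colData column(s): ", paste(miss, collapse = ", ")))
  if (ncol(object) > 0L) {
    bad <- which(!is.finite(vol) | vol < 0, arr.ind = TRUE)
    if (nrow(bad))
      msg <- c(msg, sprintf(
        "non-finite or negative volume for subject '%s', region '%s'",
        cd$subject_id[bad[1L, 2L]], rownames(vol)[bad[1L, 1L]]))
    age <- cd$age
    if (anyNA(age) || any(age != round(age)))
      msg <- c(msg, "age must be integer years with no missing values")
    else {
      out <- which(age < AGE_MIN | age > AGE_MAX)
      if (length(out))
        msg <- c(msg, sprintf(
          "age outside [%d, %d] for subject(s): %s", AGE_MIN, AGE_MAX,
          paste(head(cd$subject_id[out], 5L), collapse = ", ")))
    }
    badtiv <- which(!is.finite(cd$tiv) | cd$tiv <= 0)
    if (length(badtiv))
      msg <- c(msg, sprintf("tiv must be > 0; offending subject(s): %s",
                            paste(head(cd$subject_id[badtiv], 5L),
                                  collapse = ", ")))
    badsex <- which(!cd$sex %in% c("male", "female"))
    if (length(badsex))
      msg <- c(msg, sprintf("sex must be 'male' or 'female'; subject(s): %s",
                            paste(head(cd$subject_id[badsex], 5L),
                                  collapse = ", ")))
    if (anyDuplicated(cd$subject_id))
      msg <- c(msg, "subject_id values must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MorphCohort
#'
#' @param volumes Numeric matrix of raw regional volumes (mm^3), subjects in
#'   rows and regions in columns, or the transpose (regions x subjects) if
#'   \code{regionsAsRows = TRUE}. Column names must match the atlas; columns
#'   are re-ordered to atlas order.
#' @param subjects data.frame with columns \code{subject_id}, \code{age},
#'   \code{sex}, \code{group}, \code{tiv}, one row per subject.
#' @param atlas Atlas data.frame ([dkAsegAtlas()] by default).
#' @param name Cohort name stored in \code{metadata()}.
#' @param regionsAsRows Set \code{TRUE} when \code{volumes} is already
#'   regions x subjects.
#' @return A validated \linkS4class{MorphCohort}.
#' @examples
#' cohort <- simulateReferenceCohort(simulationSpec(nPerGroup = c(HC = 5)))
#' cohort
#' @export
MorphCohort <- function(volumes, subjects, atlas = dkAsegAtlas(),
                        name = "cohort", regionsAsRows = FALSE) {
  checkAtlas101(atlas)
  if (!regionsAsRows) volumes <- t(volumes)
  if (is.null(rownames(volumes)))
    stop("volumes must carry region names")
  miss <- setdiff(atlas$name, rownames(volumes))
  if (length(miss))
    stop("missing region column(s): ", paste(head(miss, 5L), collapse = ", "))
  volumes <- volumes[atlas$name, , drop = FALSE]
  subjects$age <- as.integer(subjects$age)
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$sex <- as.character(subjects$sex)
  subjects$group <- as.character(subjects$group)
  colnames(volumes) <- subjects$subject_id
  rd <- DataFrame(atlas, row.names = atlas$name)
  se <- SummarizedExperiment(assays = list(volumes = volumes),
                             rowData = rd,
                             colData = DataFrame(subjects,
                                                 row.names = subjects$subject_id))
  obj <- new("MorphCohort", se)
  metadata(obj)$name <- name
  validObject(obj)
  obj
}

#' @describeIn MorphCohort-accessors Cohort name.
#' @export
cohortName <- function(x) metadata(x)$name

#' Accessors for MorphCohort
#'
#' Small convenience accessors over the underlying SummarizedExperiment:
#' \code{volumeMatrix} returns subjects x regions (the orientation the
#' statistical code works in), the others return per-subject vectors.
#'
#' @param x A \linkS4class{MorphCohort}.
#' @name MorphCohort-accessors
#' @return \code{volumeMatrix}: numeric matrix (subjects x regions);
#'   the others: vectors of length \code{ncol(x)}.
NULL

#' @describeIn MorphCohort-accessors Raw volumes, subjects x regions.
#' @export
volumeMatrix <- function(x) t(assay(x, "volumes"))

#' @describeIn MorphCohort-accessors Integer ages.
#' @export
subjectAges <- function(x) colData(x)$age

#' @describeIn MorphCohort-accessors Sex labels.
#' @export
subjectSex <- function(x) colData(x)$sex

#' @describeIn MorphCohort-accessors Diagnostic group labels.
#' @export
subjectGroups <- function(x) colData(x)$group

#' @describeIn MorphCohort-accessors Total intracranial volumes.
#' @export
subjectTIV <- function(x) colData(x)$tiv

#' @describeIn MorphCohort-accessors Subject identifiers.
#' @export
subjectIDs <- function(x) colData(x)$subject_id

#' @describeIn MorphCohort-accessors Atlas as a data.frame.
#' @export
cohortAtlas <- function(x) as.data.frame(rowData(x))

setMethod("show", "MorphCohort", function(object) {
  cat(sprintf("MorphCohort '%s': %d regions x %d subjects\n",
              cohortName(object), nrow(object), ncol(object)))
  if (ncol(object)) {
    tab <- table(subjectGroups(object))
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
    cat(sprintf("age range: [%d, %d]\n", min(subjectAges(object)),
                max(subjectAges(object))))
  }
})

checkAtlas101 <- function(atlas) {
  checkAtlas(atlas)
  if (nrow(atlas) != 101L)
    stop("atlas must list exactly 101 regions, found ", nrow(atlas))
  invisible(atlas)
}

# bootstrap resampling: subset by (possibly repeated) subject indices and
# re-uniquify subject ids so the resampled cohort stays a valid MorphCohort
resampleCohort <- function(x, idx) {
  out <- x[, idx]
  ids <- make.unique(subjectIDs(x)[idx], sep = "#")
  colData(out)$subject_id <- ids
  colnames(out) <- ids
  out
}

#' Subset a cohort to one or more diagnostic groups
#'
#' @param x A \linkS4class{MorphCohort}.
#' @param groups Character vector of group labels to keep.
#' @return A \linkS4class{MorphCohort} with only the requested subjects.
#' @export
subsetGroups <- function(x, groups) {
  keep <- subjectGroups(x) %in% groups
  if (!any(keep))
    stop("no subjects in group(s): ", paste(groups, collapse = ", "))
  x[, keep]
}
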
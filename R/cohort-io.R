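#' Read a cohort table from CSV
#'
#' Cohort file dialect: comma-separated, UTF-8, header row naming
#' \code{subject_id}, \code{age}, \code{sex}, \code{group}, \code{tiv} and
#' all 101 atlas regions. Region columns may appear in any order; they are
#' re-ordered to atlas order on read. Validation is strict and reports every
#' offending row: fractional ages are rejected (not rounded), ages must lie
#' in \[47, 73\], TIV must be positive, volumes numeric and non-negative.
#'
#' @param path Path to a CSV cohort file.
#' @param atlas Atlas data.frame; defaults to [dkAsegAtlas()].
#' @param name Cohort name; defaults to the file base name.
#' @return A validated \linkS4class{MorphCohort}, row order preserved.
#' @seealso [writeCohortTable()] for the inverse operation.
#' @export
readCohortTable <- function(path, atlas = dkAsegAtlas(),
                            name = sub("\\.csv$", "", basename(path))) {
  checkAtlas101(atlas)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "group", "tiv")
  miss <- setdiff(c(need, atlas$name), names(df))
  if (length(miss))
    stop("cohort file '", basename(path), "' is missing column(s): ",
         paste(head(miss, 8L), collapse = ", "))
  if (nrow(df) == 0L) {
    vol <- matrix(numeric(0), 0L, 101L, dimnames = list(NULL, atlas$name))
    subj <- data.frame(subject_id = character(0), age = integer(0),
                       sex = character(0), group = character(0),
                       tiv = numeric(0), stringsAsFactors = FALSE)
    return(MorphCohort(vol, subj, atlas = atlas, name = name))
  }
  probs <- character()
  for (col in c("age", "tiv", atlas$name)) {
    if (!is.numeric(df[[col]])) {
      badrow <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      probs <- c(probs, sprintf("non-numeric '%s' in row(s) %s", col,
                                paste(head(badrow, 5L), collapse = ", ")))
    }
  }
  if (length(probs)) stop(paste(probs, collapse = "; "))
  frac <- which(df$age != round(df$age))
  if (length(frac))
    probs <- c(probs, sprintf("fractional age in row(s) %s",
                              paste(head(frac, 5L), collapse = ", ")))
  out <- which(df$age < AGE_MIN | df$age > AGE_MAX)
  if (length(out))
    probs <- c(probs, sprintf("age outside [%d, %d] in row(s) %s",
                              AGE_MIN, AGE_MAX,
                              paste(head(out, 5L), collapse = ", ")))
  badtiv <- which(df$tiv <= 0)
  if (length(badtiv))
    probs <- c(probs, sprintf("tiv <= 0 in row(s) %s",
                              paste(head(badtiv, 5L), collapse = ", ")))
  if (length(probs)) stop(paste(probs, collapse = "; "))
  vol <- as.matrix(df[, atlas$name, drop = FALSE])
  MorphCohort(volumes = vol,
              subjects = df[, need, drop = FALSE],
              atlas = atlas, name = name)
}

#' Write a cohort table to CSV
#'
#' Inverse of [readCohortTable()]: the round trip reproduces the cohort
#' exactly (volumes are written with full precision). An empty cohort
#' produces a header-only file.
#'
#' @param cohort A \linkS4class{MorphCohort}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeCohortTable <- function(cohort, path) {
  stopifnot(is(cohort, "MorphCohort"))
  cd <- as.data.frame(colData(cohort))
  vol <- volumeMatrix(cohort)
  df <- cbind(cd[, c("subject_id", "age", "sex", "group", "tiv"),
                 drop = FALSE],
              as.data.frame(vol, check.names = FALSE))
  # 17 significant digits make the numeric round trip bit-exact
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Demographic balance tests across diagnostic groups
#'
#' Checks whether the diagnostic groups of one cohort are balanced on age
#' and sex, the standard sanity check before group comparisons: a one-way
#' ANOVA for age across groups and a chi-square test of homogeneity
#' (no continuity correction) for the sex x group table, plus per-group
#' summary counts (n, mean and SD of age, sex counts).
#'
#' @param cohort A \linkS4class{MorphCohort} with at least two diagnostic
#'   groups of at least two subjects each.
#' @return A list of class \code{"BalanceReport"} with elements
#'   \code{age_anova_p}, \code{sex_chisq_p}, and \code{summary} (data.frame:
#'   group, n, age_mean, age_sd, n_male, n_female).
#' @export
demographicBalanceTests <- function(cohort) {
  grp <- factor(subjectGroups(cohort))
  if (nlevels(grp) < 2L)
    stop("balance tests need at least two diagnostic groups")
  sizes <- table(grp)
  if (any(sizes < 2L))
    stop("every group needs >= 2 subjects; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  age <- subjectAges(cohort)
  sex <- factor(subjectSex(cohort), levels = c("male", "female"))
  ss_between <- sum(tapply(age, grp, function(a) length(a) * (mean(a) - mean(age))^2))
  if (ss_between == 0) {
    p_age <- 1
  } else {
    p_age <- summary(aov(age ~ grp))[[1L]][["Pr(>F)"]][1L]
  }
  tab <- table(sex, grp)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  p_sex <- if (is.nan(chi$statistic) || chi$statistic == 0) 1 else
    unname(chi$p.value)
  summ <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- grp == g
    data.frame(group = g, n = sum(i), age_mean = mean(age[i]),
               age_sd = stats::sd(age[i]),
               n_male = sum(sex[i] == "male"),
               n_female = sum(sex[i] == "female"),
               stringsAsFactors = FALSE)
  }))
  structure(list(age_anova_p = unname(p_age), sex_chisq_p = p_sex,
                 summary = summ),
            class = "BalanceReport")
}

#' @export
print.BalanceReport <- function(x, ...) {
  cat(sprintf("Demographic balance: age ANOVA p = %.3g, sex chi-square p = %.3g\n",
              x$age_anova_p, x$sex_chisq_p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
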
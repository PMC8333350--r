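test_that("default atlas has the canonical region structure", {
  atlas <- dkAsegAtlas()
  expect_equal(nrow(atlas), 101L)
  expect_equal(sum(atlas$kind == "cortical"), 68L)
  expect_equal(sum(atlas$kind == "subcortical"), 33L)
  expect_false(anyDuplicated(atlas$name) > 0)
})

test_that("atlas files round-trip through readAtlas", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(dkAsegAtlas()$name, path)
  got <- readAtlas(path)
  expect_equal(got$name, dkAsegAtlas()$name)
  expect_equal(got$kind, dkAsegAtlas()$kind)
})

test_that("cohort tables round-trip bit-exactly", {
  co <- toyReference(n = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohortTable(co, path)
  back <- readCohortTable(path, name = cohortName(co))
  expect_identical(volumeMatrix(back), volumeMatrix(co))
  expect_identical(subjectTIV(back), subjectTIV(co))
  expect_identical(subjectAges(back), subjectAges(co))
  expect_identical(subjectSex(back), subjectSex(co))
  expect_identical(subjectGroups(back), subjectGroups(co))
  expect_identical(subjectIDs(back), subjectIDs(co))
})

test_that("region column order is normalised on read", {
  co <- handCohort()
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohortTable(co, path)
  df <- read.csv(path, check.names = FALSE)
  shuffled <- df[, c(1:5, sample(6:106))]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(shuffled, path2, row.names = FALSE, quote = FALSE)
  expect_equal(volumeMatrix(readCohortTable(path2)),
               volumeMatrix(readCohortTable(path)))
})

test_that("edge cohorts survive the round trip", {
  co <- toyReference(n = 3)
  one <- co[, 1]
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeCohortTable(one, p1)
  expect_equal(ncol(readCohortTable(p1)), 1L)
  empty <- co[, 0]
  p0 <- withr::local_tempfile(fileext = ".csv")
  writeCohortTable(empty, p0)
  expect_equal(ncol(readCohortTable(p0)), 0L)
  expect_equal(length(readLines(p0)), 1L)  # header only
})

test_that("validation names the offending column and rows", {
  co <- handCohort()
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohortTable(co, path)
  df <- read.csv(path, check.names = FALSE)
  p2 <- withr::local_tempfile(fileext = ".csv")

  write.csv(df[, setdiff(names(df), "tiv")], p2, row.names = FALSE)
  expect_error(readCohortTable(p2), "tiv")

  bad <- df; bad$age[2] <- 80
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readCohortTable(p2), "age outside \\[47, 73\\].*2")

  bad <- df; bad$age[1] <- 52.5
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readCohortTable(p2), "fractional age")

  bad <- df; bad$tiv[3] <- -1
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readCohortTable(p2), "tiv <= 0")

  bad <- df; bad[[10]][1] <- "oops"
  write.csv(bad, p2, row.names = FALSE)
  expect_error(readCohortTable(p2), "non-numeric")
})

test_that("cohort validity rejects invalid subject records", {
  atlas <- dkAsegAtlas()
  vol <- matrix(1000, 2, 101, dimnames = list(NULL, atlas$name))
  subj <- data.frame(subject_id = c("a", "b"), age = c(50L, 60L),
                     sex = c("male", "unknown"), group = "HC", tiv = 1.4e6)
  expect_error(MorphCohort(vol, subj), "sex")
  subj$sex <- c("male", "female"); subj$age <- c(46L, 60L)
  expect_error(MorphCohort(vol, subj), "age")
  subj$age <- c(50L, 60L); subj$tiv <- c(0, 1.4e6)
  expect_error(MorphCohort(vol, subj), "tiv")
})

test_that("balance tests match closed-form oracles", {
  mk <- function(ages, sex, grp)
    handCohort(ages = ages, sex = sex, group = grp,
               tiv = rep(1.5e6, length(ages)))
  # identical age lists in both groups: zero between-group variance, p = 1
  co <- mk(rep(c(50L, 60L, 70L), 2),
           rep(c("male", "female", "male"), 2),
           rep(c("HC", "AD"), each = 3))
  rep1 <- demographicBalanceTests(co)
  expect_equal(rep1$age_anova_p, 1)
  # identical sex ratios: chi-square statistic 0, p = 1
  expect_equal(rep1$sex_chisq_p, 1)

  # separated ages {50,51,52} vs {70,71,72}: hand-computed F oracle
  co2 <- mk(c(50L, 51L, 52L, 70L, 71L, 72L),
            rep(c("male", "female"), 3),
            rep(c("HC", "AD"), each = 3))
  rep2 <- demographicBalanceTests(co2)
  # SSB = 600 (df 1), SSW = 4 (df 4) => F = 600, p = P(F(1,4) > 600)
  expect_equal(rep2$age_anova_p, pf(600, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(rep2$age_anova_p, 0.01)

  # summaries mirror the cohort exactly
  expect_equal(rep2$summary$n, c(3L, 3L))
  expect_equal(rep2$summary$age_mean[rep2$summary$group == "HC"], 51)
})

test_that("balance tests are invariant to row order and guard group sizes", {
  co <- handCohort(ages = c(50L, 55L, 60L, 65L, 70L, 73L),
                   sex = rep(c("male", "female"), 3),
                   group = rep(c("HC", "AD"), 3))
  perm <- co[, c(4, 2, 6, 1, 3, 5)]
  a <- demographicBalanceTests(co)
  b <- demographicBalanceTests(perm)
  expect_equal(a$age_anova_p, b$age_anova_p)
  expect_equal(a$sex_chisq_p, b$sex_chisq_p)

  expect_error(demographicBalanceTests(subsetGroups(co, "HC")),
               "two diagnostic groups")
  tiny <- co[, 1:3]   # AD group of size 1
  expect_error(demographicBalanceTests(tiny), ">= 2 subjects")
})
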
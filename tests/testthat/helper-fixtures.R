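# Shared fixtures. Everything is generated in code; the heavy seeded runs
# (full desk-scale bootstrap, null calibration, a single trained reference
# model) are computed once per test session and cached in this environment
# so several test files can assert against the same run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# small all-HC cohort for plumbing tests
toyReference <- function(n = 60, seed = 11) {
  simulateReferenceCohort(simulationSpec(nPerGroup = c(HC = n), seed = seed))
}

# tiny hand-built cohort with controllable demographics
handCohort <- function(ages = c(50L, 60L, 70L),
                       sex = c("male", "female", "male"),
                       group = rep("HC", length(ages)),
                       tiv = rep(1.5e6, length(ages)),
                       seed = 1) {
  set.seed(seed)
  atlas <- dkAsegAtlas()
  n <- length(ages)
  vol <- matrix(abs(rnorm(n * 101, 5000, 500)), n, 101,
                dimnames = list(NULL, atlas$name))
  MorphCohort(vol, data.frame(subject_id = sprintf("H%02d", seq_len(n)),
                              age = ages, sex = sex, group = group,
                              tiv = tiv, stringsAsFactors = FALSE),
              atlas = atlas, name = "hand")
}

# fast AAE config for plumbing-level tests (not used for scientific claims)
fastConfig <- function(...) aaeConfig(epochs = 8L, batchSize = 32L, ...)

# a single reference model at desk scale, shared by the slower checks
deskModel <- function() {
  cached("deskModel", {
    ref <- deskReference()
    trainAAE(ref, aaeConfig(seed = 1L))
  })
}

deskReference <- function() {
  cached("deskReference",
         simulateReferenceCohort(simulationSpec(nPerGroup = c(HC = 2000),
                                                seed = 101)))
}

gradedClinical <- function() {
  cached("gradedClinical", {
    maps <- list(EMCI = adEffectMap(0.3), LMCI = adEffectMap(0.6),
                 AD = adEffectMap(1.0))
    simulateClinicalCohort(
      simulationSpec(nPerGroup = c(HC = 150, EMCI = 150, LMCI = 150,
                                   AD = 150),
                     effectMaps = maps, seed = 102),
      name = "clinical")
  })
}

# the full desk-scale bootstrap evaluation (reference n = 2000, B = 20)
deskBootstrap <- function() {
  cached("deskBootstrap",
         bootstrapNormativeEvaluation(deskReference(),
                                      gradedClinical()$cohort,
                                      aaeConfig(), B = 20L, seed = 103L))
}

# null-calibration bootstrap: clinical stage with zero effect everywhere
nullBootstrap <- function() {
  cached("nullBootstrap", {
    ref <- simulateReferenceCohort(simulationSpec(nPerGroup = c(HC = 1000),
                                                  seed = 201))
    cl <- simulateClinicalCohort(
      simulationSpec(nPerGroup = c(HC = 120, PSEUDO = 120),
                     effectMaps = list(PSEUDO = adEffectMap(0)),
                     seed = 202), name = "nullclin")
    list(result = bootstrapNormativeEvaluation(ref, cl$cohort,
                                               aaeConfig(epochs = 100L),
                                               B = 12L, seed = 203L),
         truth = cl$truth)
  })
}
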
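#' Disease-stage effect map for Alzheimer's-type atrophy
#'
#' Per-region fractional volume changes emulating the morphometry of the
#' Alzheimer's continuum at a given severity: atrophy (negative fractions)
#' of the medial temporal lobe — hippocampus, amygdala, entorhinal and
#' parahippocampal cortex — and enlargement (positive fractions) of the
#' ventricular system — lateral ventricles, temporal horns (inferior
#' lateral ventricles) and 3rd ventricle. Effects scale linearly with
#' \code{severity}; all other regions are untouched. At severity 1 the
#' defaults are 20-30\% medial-temporal loss and 30-50\% ventricular
#' enlargement, a qualitative emulation of the atrophy pattern reported in
#' AD morphometry, not fitted values.
#'
#' @param severity Scalar in \[0, 1\]; disease stage intensity.
#' @param atlas Atlas data.frame.
#' @return A list of class \code{"EffectMap"}: \code{effects} (named numeric
#'   vector over all atlas regions, fraction of baseline volume),
#'   \code{severity}, and \code{affected} (names of regions with non-zero
#'   effect).
#' @examples
#' m <- adEffectMap(1)
#' m$effects["Left-Hippocampus"]   # -0.25
#' @export
adEffectMap <- function(severity, atlas = dkAsegAtlas()) {
  if (!is.numeric(severity) || length(severity) != 1L ||
      severity < 0 || severity > 1)
    stop("severity must be a scalar in [0, 1]")
  full <- c(
    "Left-Hippocampus"   = -0.25, "Right-Hippocampus"  = -0.25,
    "Left-Amygdala"      = -0.22, "Right-Amygdala"     = -0.22,
    "lh_entorhinal"      = -0.28, "rh_entorhinal"      = -0.28,
    "lh_parahippocampal" = -0.20, "rh_parahippocampal" = -0.20,
    "Left-Lateral-Ventricle"  = 0.40, "Right-Lateral-Ventricle" = 0.40,
    "Left-Inf-Lat-Vent"  = 0.50, "Right-Inf-Lat-Vent" = 0.50,
    "3rd-Ventricle"      = 0.30)
  effects <- setNames(numeric(nrow(atlas)), atlas$name)
  effects[names(full)] <- full * severity
  structure(list(effects = effects, severity = severity,
                 affected = names(full)),
            class = "EffectMap")
}

#' Construct a custom effect map
#'
#' General constructor for per-region fractional volume changes; see
#' [adEffectMap()] for the canonical Alzheimer's-type default. Regions not
#' named in \code{effects} are unaffected.
#'
#' @param effects Named numeric vector of fractional changes in
#'   (-0.9, 0.9); names must be atlas regions.
#' @param severity Stage severity scalar recorded with the map.
#' @param atlas Atlas data.frame.
#' @return A list of class \code{"EffectMap"}.
#' @export
effectMap <- function(effects, severity = 1, atlas = dkAsegAtlas()) {
  bad <- setdiff(names(effects), atlas$name)
  if (length(bad))
    stop("unknown region(s) in effect map: ", paste(head(bad, 5L),
                                                    collapse = ", "))
  if (any(abs(effects) >= 0.9))
    stop("fractional effects must lie in (-0.9, 0.9)")
  full <- setNames(numeric(nrow(atlas)), atlas$name)
  full[names(effects)] <- effects
  structure(list(effects = full, severity = severity,
                 affected = names(effects)[effects != 0]),
            class = "EffectMap")
}

#' Simulation specification for synthetic morphometry cohorts
#'
#' Bundles every generative parameter of the synthetic cohort model. A
#' subject's raw volume in region \eqn{r} is
#' \deqn{v_r = b_r \cdot \frac{tiv}{\bar{tiv}} \cdot
#'   (1 + s_r (age - 60) + m_r [male]) \cdot (1 + e_r) \cdot e^{\epsilon},
#'   \quad \epsilon \sim N(0, \sigma^2),}
#' with \eqn{b_r} the baseline mean volume, \eqn{s_r} an age slope
#' (fraction per year, centred at 60), \eqn{m_r} a sex offset, \eqn{e_r}
#' the stage effect from an [adEffectMap()] and \eqn{\sigma} the
#' multiplicative log-normal noise SD. Ages are uniform over the integer
#' range, sex is Bernoulli, TIV is Gaussian. Defaults emulate an ageing
#' cohort: slow cortical/subcortical atrophy with age, ventricular
#' enlargement with age, ~10\% between-subject coefficient of variation.
#'
#' @param nPerGroup Named integer vector of subjects per group, e.g.
#'   \code{c(HC = 200, EMCI = 100)}. Names are the diagnostic labels.
#' @param ageRange Integer vector of length 2 inside \[47, 73\].
#' @param maleRatio Probability a subject is male.
#' @param baseline Named numeric vector of per-region baseline mean volumes
#'   (mm^3); defaults to a plausible deterministic profile over the atlas.
#' @param ageSlope Named numeric vector, fractional change per year of age.
#' @param sexOffset Named numeric vector, fractional offset for males.
#' @param noiseSd Log-normal noise SD (between-subject variability).
#' @param tivMean,tivSd TIV distribution parameters (mm^3).
#' @param effectMaps Named list mapping each non-HC group label to an
#'   \code{EffectMap} (see [adEffectMap()]). HC always gets zero effect.
#' @param atlas Atlas data.frame.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(nPerGroup = c(HC = 100),
                           ageRange = c(47L, 73L),
                           maleRatio = 0.47,
                           baseline = NULL,
                           ageSlope = NULL,
                           sexOffset = NULL,
                           noiseSd = 0.10,
                           tivMean = 1.5e6, tivSd = 1.3e5,
                           effectMaps = list(),
                           atlas = dkAsegAtlas(),
                           seed = 1L) {
  checkAtlas101(atlas)
  if (is.null(names(nPerGroup)) || any(!nzchar(names(nPerGroup))))
    stop("nPerGroup must be a named vector of group sizes")
  if (any(nPerGroup < 0)) stop("group sizes must be >= 0")
  if (ageRange[1L] < AGE_MIN || ageRange[2L] > AGE_MAX ||
      ageRange[1L] > ageRange[2L])
    stop(sprintf("ageRange must lie within [%d, %d]", AGE_MIN, AGE_MAX))
  if (noiseSd < 0 || tivSd < 0) stop("SDs must be >= 0")
  if (is.null(baseline)) baseline <- defaultBaselineVolumes(atlas)
  if (is.null(ageSlope)) ageSlope <- defaultAgeSlopes(atlas)
  if (is.null(sexOffset)) {
    sexOffset <- setNames(rep(0.02, nrow(atlas)), atlas$name)
  }
  baseline <- baseline[atlas$name]; ageSlope <- ageSlope[atlas$name]
  sexOffset <- sexOffset[atlas$name]
  if (anyNA(baseline) || anyNA(ageSlope) || anyNA(sexOffset))
    stop("baseline/ageSlope/sexOffset must cover every atlas region")
  for (g in names(effectMaps))
    if (!inherits(effectMaps[[g]], "EffectMap"))
      stop("effectMaps[['", g, "']] is not an EffectMap")
  structure(list(nPerGroup = nPerGroup, ageRange = as.integer(ageRange),
                 maleRatio = maleRatio, baseline = baseline,
                 ageSlope = ageSlope, sexOffset = sexOffset,
                 noiseSd = noiseSd, tivMean = tivMean, tivSd = tivSd,
                 effectMaps = effectMaps, atlas = atlas, seed = seed),
            class = "SimulationSpec")
}

# Plausible deterministic baseline volumes (mm^3): literature-scale values
# for the clinically central structures, smooth profiles elsewhere. Only
# relative (per-region) statistics matter downstream, but realistic scales
# keep the TIV-relative features in a sensible range.
defaultBaselineVolumes <- function(atlas = dkAsegAtlas()) {
  b <- setNames(numeric(nrow(atlas)), atlas$name)
  cort <- atlas$kind == "cortical"
  # cortical regions: 2,000-24,000 mm^3, deterministic spread
  b[cort] <- round(seq(2400, 24000, length.out = sum(cort)))
  named <- c(
    "Lateral-Ventricle" = 9000, "Inf-Lat-Vent" = 400,
    "Cerebellum-White-Matter" = 14000, "Cerebellum-Cortex" = 53000,
    "Thalamus-Proper" = 7500, "Caudate" = 3600, "Putamen" = 5200,
    "Pallidum" = 1700, "Hippocampus" = 4200, "Amygdala" = 1700,
    "Accumbens-area" = 600, "VentralDC" = 4000, "vessel" = 50,
    "choroid-plexus" = 1600)
  for (nm in names(named)) {
    b[paste0("Left-", nm)] <- named[[nm]]
    b[paste0("Right-", nm)] <- named[[nm]]
  }
  b["3rd-Ventricle"] <- 1100; b["4th-Ventricle"] <- 1800
  b["Brain-Stem"] <- 21000; b["CSF"] <- 1000; b["Optic-Chiasm"] <- 200
  b
}

# Fractional volume change per year of age: slow grey-matter atrophy,
# ventricular expansion — the dominant normal-ageing signals the
# conditioned decoder has to absorb.
defaultAgeSlopes <- function(atlas = dkAsegAtlas()) {
  s <- setNames(rep(-0.003, nrow(atlas)), atlas$name)
  s[atlas$kind == "subcortical"] <- -0.002
  vent <- grepl("Ventricle|Inf-Lat-Vent|CSF", atlas$name)
  s[vent] <- 0.02
  s
}

simulateSubjects <- function(spec, groupLabels) {
  n <- length(groupLabels)
  ages <- spec$ageRange[1L] +
    sample.int(spec$ageRange[2L] - spec$ageRange[1L] + 1L, n,
               replace = TRUE) - 1L
  sex <- ifelse(rbinom(n, 1L, spec$maleRatio) == 1L, "male", "female")
  tiv <- rnorm(n, spec$tivMean, spec$tivSd)
  while (any(tiv <= 0)) {                      # resample, never clip
    bad <- tiv <= 0
    tiv[bad] <- rnorm(sum(bad), spec$tivMean, spec$tivSd)
  }
  p <- length(spec$baseline)
  det <- matrix(spec$baseline, n, p, byrow = TRUE) *
    (tiv / spec$tivMean) *
    (1 + outer(ages - 60, spec$ageSlope) +
       outer(as.numeric(sex == "male"), spec$sexOffset))
  for (g in unique(groupLabels)) {
    if (g == "HC") next
    em <- spec$effectMaps[[g]]
    if (is.null(em)) stop("no EffectMap declared for clinical stage '", g, "'")
    i <- groupLabels == g
    det[i, ] <- det[i, ] * matrix(1 + em$effects, sum(i), p, byrow = TRUE)
  }
  eps <- matrix(rnorm(n * p, 0, spec$noiseSd), n, p)
  vol <- det * exp(eps)
  # the deterministic part can go negative under extreme slopes/effects;
  # resample the noise term would not fix that, so guard the determinate part
  if (any(det <= 0))
    stop("generative parameters produced non-positive expected volumes")
  colnames(vol) <- names(spec$baseline)
  list(volumes = vol,
       subjects = data.frame(
         subject_id = sprintf("S%05d", seq_len(n)),
         age = ages, sex = sex, group = groupLabels, tiv = tiv,
         stringsAsFactors = FALSE))
}

#' Generate a healthy reference cohort
#'
#' Draws an all-HC cohort from the generative model described in
#' [simulationSpec()]. Deterministic given the spec's seed.
#'
#' @param spec A \code{SimulationSpec} whose \code{nPerGroup} contains only
#'   \code{HC}.
#' @param name Cohort name.
#' @return A \linkS4class{MorphCohort}.
#' @export
simulateReferenceCohort <- function(spec, name = "reference") {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (!identical(names(spec$nPerGroup), "HC"))
    stop("a reference cohort must contain the HC group only")
  set.seed(spec$seed)
  sim <- simulateSubjects(spec, rep("HC", spec$nPerGroup[["HC"]]))
  sim$subjects$subject_id <- paste0("REF-", sim$subjects$subject_id)
  MorphCohort(sim$volumes, sim$subjects, atlas = spec$atlas, name = name)
}

#' Generate a clinical cohort with graded disease stages
#'
#' Draws a cohort containing an HC group plus one or more clinical stages,
#' each with its declared [adEffectMap()]; HC members receive zero effect.
#' Returns the cohort together with the ground-truth manifest needed to
#' score region-localization performance downstream.
#'
#' @param spec A \code{SimulationSpec} with \code{nPerGroup} naming HC and
#'   at least one clinical stage present in \code{effectMaps}.
#' @param name Cohort name.
#' @return A list with elements \code{cohort} (\linkS4class{MorphCohort})
#'   and \code{truth} (list: \code{effectMaps}, \code{affected} region names
#'   per stage, \code{seed}).
#' @export
simulateClinicalCohort <- function(spec, name = "clinical") {
  stopifnot(inherits(spec, "SimulationSpec"))
  stages <- setdiff(names(spec$nPerGroup), "HC")
  if (!length(stages))
    stop("a clinical cohort needs at least one non-HC stage")
  missing_maps <- setdiff(stages, names(spec$effectMaps))
  if (length(missing_maps))
    stop("stage(s) without an EffectMap: ",
         paste(missing_maps, collapse = ", "))
  set.seed(spec$seed)
  labels <- rep(names(spec$nPerGroup), times = spec$nPerGroup)
  sim <- simulateSubjects(spec, labels)
  sim$subjects$subject_id <- paste0("CLN-", sim$subjects$subject_id)
  cohort <- MorphCohort(sim$volumes, sim$subjects, atlas = spec$atlas,
                        name = name)
  truth <- list(
    effectMaps = spec$effectMaps[stages],
    affected = lapply(spec$effectMaps[stages], function(m) m$affected),
    seed = spec$seed)
  list(cohort = cohort, truth = truth)
}
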
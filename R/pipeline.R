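#' Default pipeline configuration
#'
#' Desk-scale configuration of the end-to-end experiment: a synthetic
#' reference cohort of 2,000 healthy controls, two synthetic clinical
#' cohorts with 150 subjects per group (HC plus EMCI/LMCI/AD analogues at
#' graded severities 0.3 / 0.6 / 1.0), B = 20 normative bootstrap
#' iterations and b = 50 classifier bootstrap iterations, with the
#' reference AAE settings (200 epochs, batch 256). The reference-scale
#' analysis this emulates uses 11,034 controls and 1,000 iterations; the
#' desk-scale run finishes in minutes on one CPU. Every entry can be
#' overridden from a YAML file via [readPipelineConfig()].
#'
#' @return Nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    name = "desk-scale",
    outdir = "aaenorm-results",
    seed = 1L,
    simulation = list(
      n_reference = 2000L,
      n_per_group = c(HC = 150L, EMCI = 150L, LMCI = 150L, AD = 150L),
      severities = c(EMCI = 0.3, LMCI = 0.6, AD = 1.0),
      noise_sd = 0.10,
      n_clinical_cohorts = 2L),
    aae = list(epochs = 200L, batch_size = 256L, latent_dim = 20L,
               base_lr = 1e-4, max_lr = 5e-3, lr_gamma = 0.98,
               adv_weight = 1.0),
    bootstrap = list(B = 20L, b = 50L, level = 0.95, size_offset = 0L),
    contrasts = "AD",
    verbose = TRUE)
}

#' Read a pipeline configuration file
#'
#' YAML configuration; any field absent from the file keeps its
#' [defaultPipelineConfig()] value (recursive merge).
#'
#' @param path Path to a YAML file, or \code{NULL} for pure defaults.
#' @return Nested configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  mergeRec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- mergeRec(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- mergeRec(cfg, user)
  for (blk in c("simulation", "bootstrap"))
    for (nm in names(cfg[[blk]]))
      if (is.list(cfg[[blk]][[nm]]))
        cfg[[blk]][[nm]] <- unlist(cfg[[blk]][[nm]])
  cfg
}

pipelineAAEConfig <- function(config, seed) {
  a <- config$aae
  aaeConfig(epochs = a$epochs, batchSize = a$batch_size,
            latentDim = a$latent_dim, baseLr = a$base_lr, maxLr = a$max_lr,
            lrGamma = a$lr_gamma, advWeight = a$adv_weight, seed = seed)
}

manifestNew <- function(config) {
  list(package_version = as.character(utils::packageVersion("aaenorm")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       config = config, stages = list(), files = list())
}

manifestStage <- function(manifest, stage, seed, status = "done") {
  manifest$stages[[stage]] <- list(seed = seed, status = status)
  manifest
}

manifestFiles <- function(manifest, paths) {
  for (p in paths)
    manifest$files[[basename(p)]] <- list(path = p,
                                          md5 = unname(tools::md5sum(p)))
  manifest
}

manifestWrite <- function(manifest, outdir) {
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

simulationSpecs <- function(config) {
  sim <- config$simulation
  maps <- lapply(sim$severities, adEffectMap)
  refSpec <- simulationSpec(nPerGroup = c(HC = sim$n_reference),
                            noiseSd = sim$noise_sd,
                            seed = deriveSeed(config$seed, "reference", 0L))
  k <- max(1L, as.integer(sim$n_clinical_cohorts))
  clinSpecs <- lapply(seq_len(k), function(i)
    simulationSpec(nPerGroup = sim$n_per_group, noiseSd = sim$noise_sd,
                   effectMaps = maps,
                   seed = deriveSeed(config$seed, "clinical", i)))
  list(reference = refSpec, clinical = clinSpecs)
}

#' Pipeline stage: simulate cohorts
#'
#' Writes the reference cohort CSV, one CSV per clinical cohort, the
#' ground-truth sidecar (JSON) and the run manifest into
#' \code{config$outdir}. Byte-identical outputs under a fixed seed.
#'
#' @param config Configuration list (see [defaultPipelineConfig()]).
#' @return Invisibly, the vector of written cohort file paths.
#' @export
runSimulate <- function(config = defaultPipelineConfig()) {
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  specs <- simulationSpecs(config)
  paths <- character()
  ref <- simulateReferenceCohort(specs$reference, name = "reference")
  p <- file.path(outdir, "reference.csv")
  writeCohortTable(ref, p); paths <- c(paths, p)
  truths <- list()
  for (i in seq_along(specs$clinical)) {
    nm <- paste0("clinical", LETTERS[i])
    cl <- simulateClinicalCohort(specs$clinical[[i]], name = nm)
    p <- file.path(outdir, paste0(nm, ".csv"))
    writeCohortTable(cl$cohort, p); paths <- c(paths, p)
    truths[[nm]] <- list(affected = cl$truth$affected,
                         seed = cl$truth$seed,
                         severities = lapply(cl$truth$effectMaps,
                                             function(m) m$severity))
  }
  gt <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(truths, gt, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- manifestNew(config)
  manifest <- manifestStage(manifest, "simulate", config$seed)
  manifest <- manifestFiles(manifest, c(paths, gt))
  manifestWrite(manifest, outdir)
  if (isTRUE(config$verbose))
    message("simulate: wrote ", length(paths), " cohort file(s) to ", outdir)
  invisible(paths)
}

#' Pipeline stage: train the normative model
#'
#' Trains one AAE on the full reference cohort and writes the model
#' artefact (with checksum sidecar) and its training log.
#'
#' @param config Configuration list.
#' @param referencePath Reference cohort CSV; default from the outdir.
#' @return Invisibly, the artefact path.
#' @export
runTrain <- function(config = defaultPipelineConfig(),
                     referencePath = file.path(config$outdir,
                                               "reference.csv")) {
  ref <- readCohortTable(referencePath)
  seed <- deriveSeed(config$seed, "train", 0L)
  model <- trainAAE(ref, pipelineAAEConfig(config, seed),
                    verbose = isTRUE(config$verbose))
  path <- file.path(config$outdir, "aae_model.rds")
  saveAAEModel(model, path)
  logPath <- file.path(config$outdir, "training_log.csv")
  write.csv(model@trainLog, logPath, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: score a cohort against a trained model
#'
#' @param config Configuration list.
#' @param modelPath Path to an artefact written by [runTrain()].
#' @param cohortPath CSV cohort to score.
#' @return Invisibly, the path of the written deviation table
#'   (subject_id, group, observed_deviation + one column per region).
#' @export
runScore <- function(config, modelPath, cohortPath) {
  model <- readAAEModel(modelPath)
  cohort <- readCohortTable(cohortPath)
  sc <- scoreDeviations(cohort, model)
  out <- cbind(sc, as.data.frame(attr(sc, "regionDeviations"),
                                 check.names = FALSE))
  path <- file.path(config$outdir,
                    paste0(cohortName(cohort), "_deviations.csv"))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline stage: full evaluation
#'
#' Runs both arms of the analysis on the simulated cohorts in
#' \code{config$outdir}: the bootstrap normative evaluation (group mean
#' deviations, pairwise differences, deviation-score AUCs, per-region
#' Cliff's deltas) and the 0.632+ RVM benchmark with cross-cohort
#' generalization, then the paired normative-vs-classifier AUC difference
#' CIs. Writes one CSV per summary table plus the finalised manifest.
#'
#' @param config Configuration list.
#' @return Invisibly, a list with the in-memory results
#'   (\code{normative}, \code{rvm}, \code{generalization},
#'   \code{comparison}).
#' @export
runEvaluate <- function(config = defaultPipelineConfig()) {
  outdir <- config$outdir
  ref <- readCohortTable(file.path(outdir, "reference.csv"))
  clinFiles <- list.files(outdir, pattern = "^clinical[A-Z]\\.csv$",
                          full.names = TRUE)
  if (!length(clinFiles)) stop("no clinical cohorts in ", outdir,
                               "; run runSimulate first")
  clinical <- lapply(clinFiles, readCohortTable)
  nb <- bootstrapNormativeEvaluation(
    ref, clinical, config = pipelineAAEConfig(config, 0L),
    B = config$bootstrap$B, seed = deriveSeed(config$seed, "evaluate", 0L),
    sizeOffset = config$bootstrap$size_offset,
    level = config$bootstrap$level, verbose = isTRUE(config$verbose))
  paths <- character()
  wr <- function(df, nm) {
    p <- file.path(outdir, nm)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(deviationSummary(nb), "deviation_summary.csv")
  wr(groupDifferenceSummary(nb), "group_differences.csv")
  wr(aucSummary(nb), "auc_summary.csv")
  wr(do.call(rbind, lapply(names(nb$regionDeltas), function(cn)
    regionEffectSummary(nb, cn))), "region_effects.csv")
  ## classifier arm: within-cohort 0.632+ then cross-cohort generalization
  rvmRows <- list(); genRows <- list(); cmpRows <- list()
  rvmResults <- list()
  for (ci in seq_along(clinical)) {
    cn <- cohortName(clinical[[ci]])
    for (g in config$contrasts) {
      r632 <- bootstrap632Auc(clinical[[ci]], c("HC", g),
                              b = config$bootstrap$b,
                              seed = deriveSeed(config$seed, paste0("rvm-", cn),
                                                ci),
                              level = config$bootstrap$level,
                              keepModels = TRUE)
      rvmResults[[paste(cn, g)]] <- r632
      rvmRows[[paste(cn, g)]] <- data.frame(
        cohort = cn, group = g, auc = r632$aucBootstrap,
        lower = r632$ci$lower, upper = r632$ci$upper,
        stringsAsFactors = FALSE)
      others <- clinical[-ci]
      if (length(others)) {
        gen <- crossCohortGeneralization(r632, others, targetGroup = g,
                                         level = config$bootstrap$level)
        gen$summary$train_cohort <- cn
        gen$summary$group <- g
        genRows[[paste(cn, g)]] <- gen$summary
        ## paired normative-vs-classifier comparison on the external cohorts
        for (tn in colnames(gen$aucs)) {
          normAuc <- nb$aucs[[tn]][, g]
          k <- min(length(normAuc), nrow(gen$aucs))
          d <- aucDifferenceCI(gen$aucs[seq_len(k), tn], normAuc[seq_len(k)],
                               level = config$bootstrap$level)
          cmpRows[[paste(cn, tn, g)]] <- data.frame(
            train_cohort = cn, test_cohort = tn, group = g,
            auc_diff = d$ci$point, lower = d$ci$lower, upper = d$ci$upper,
            significant = d$significant, stringsAsFactors = FALSE)
        }
      }
    }
  }
  wr(do.call(rbind, rvmRows), "rvm_auc.csv")
  if (length(genRows)) wr(do.call(rbind, genRows), "generalization.csv")
  if (length(cmpRows)) wr(do.call(rbind, cmpRows), "auc_comparison.csv")
  manifest <- manifestNew(config)
  manifest <- manifestStage(manifest, "evaluate",
                            deriveSeed(config$seed, "evaluate", 0L))
  manifest <- manifestFiles(manifest, paths)
  manifestWrite(manifest, outdir)
  if (isTRUE(config$verbose))
    message("evaluate: wrote ", length(paths), " summary table(s) to ",
            outdir)
  invisible(list(normative = nb, rvm = rvmResults,
                 generalization = if (length(genRows))
                   do.call(rbind, genRows),
                 comparison = if (length(cmpRows)) do.call(rbind, cmpRows)))
}
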
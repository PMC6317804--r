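# Config-driven end-to-end orchestration: data generation or loading,
# train/test split, hypothesis enumeration and scoring, QSAR fitting and
# evaluation, external-library screening, confusion statistics and
# similarity-stratified interpretation, with a machine-readable manifest.
# Rerunning with the same config and seed reproduces all numeric outputs
# bit-identically.

#' Default pipeline configuration
#'
#' @param seed Master seed for every stochastic stage.
#' @param mode \code{"sitesets"} (synthetic geometry tier, default) or
#'   \code{"smiles"} (compound tables through the full preparation and
#'   perception stack).
#' @return Nested configuration list; fields mirror the module parameters
#'   (hypothesis k, active fraction, tolerance and survival fraction; QSAR
#'   factors, threshold, minimum matched sites, grid spacing and margin;
#'   split strategy; similarity bands).
#' @export
pipelineConfig <- function(seed = 7, mode = c("sitesets", "smiles")) {
  mode <- match.arg(mode)
  list(
    seed = as.integer(seed),
    input = list(mode = mode, compounds = NULL, library = NULL),
    synthetic = list(nActives = 20, nDecoys = 20,
                     nLibraryActives = 10, nLibraryDecoys = 30,
                     intercept = 4.2, bonus = 1.5, noiseSD = 0.3),
    prep = list(randomSeed = as.integer(seed)),
    hypothesis = list(k = 4, minActiveFraction = 0.5, matchTolerance = 2.0,
                      survivalFraction = 0.2),
    qsar = list(factors = 3, threshold = 5.0, minSites = 3, spacing = 1.0,
                margin = 2.0, stabilityRounds = 6, holdoutFraction = 0.2),
    split = list(strategy = "random", trainFraction = 0.7),
    similarity = list(bands = defaultSimilarityBands(), radius = 2,
                      nBits = 1024))
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields fall back to \code{\link{pipelineConfig}} defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
loadPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipelineConfig(seed = user$seed %||% 7,
                         mode = user$input$mode %||% "sitesets")
  mergeList <- function(base, user) {
    for (nm in names(user)) {
      if (is.list(user[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- mergeList(base[[nm]], user[[nm]])
      else base[[nm]] <- user[[nm]]
    }
    base
  }
  mergeList(base, user)
}

#' Run the full screening pipeline
#'
#' Executes, in order: input preparation (synthetic generation or compound
#' loading + conformer preparation + site perception), train/test split,
#' common-pharmacophore enumeration and scoring with survival filtering,
#' QSAR fitting with the statistics panel, test-set evaluation, external
#' library screening with hit rates, confusion statistics against the
#' labeled subsets, and similarity-banded stratification. All artifacts are
#' written under \code{outDir} together with a manifest (config, seed, file
#' checksums).
#'
#' @param config Configuration from \code{\link{pipelineConfig}} or
#'   \code{\link{loadPipelineConfig}}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (hypotheses,
#'   model, test statistics, screening results, stratification, manifest).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- tryCatch(
    if (config$input$mode == "sitesets")
      .pipelineSyntheticInputs(config, outDir)
    else .pipelineSmilesInputs(config, outDir),
    error = function(e) stop("pipeline failed at stage [input]: ",
                             conditionMessage(e), call. = FALSE))
  res <- tryCatch(
    .pipelineCore(inputs, config, outDir),
    error = function(e) stop("pipeline failed at stage [modeling]: ",
                             conditionMessage(e), call. = FALSE))
  invisible(res)
}

# ---- synthetic (geometry tier) inputs --------------------------------------

.pipelineSyntheticInputs <- function(config, outDir) {
  sy <- config$synthetic
  gen <- generatePlantedSiteSets(nActives = sy$nActives,
                                 nDecoys = sy$nDecoys, seed = config$seed)
  act <- assignSyntheticActivities(gen$labels, intercept = sy$intercept,
                                   bonus = sy$bonus, noiseSD = sy$noiseSD,
                                   threshold = config$qsar$threshold,
                                   seed = config$seed + 1L)
  ids <- names(gen$siteSets)
  pIC50 <- stats::setNames(act$pIC50, ids)

  lib <- generatePlantedSiteSets(nActives = sy$nLibraryActives,
                                 nDecoys = sy$nLibraryDecoys,
                                 seed = config$seed + 1000L)
  names(lib$siteSets) <- paste0("lib_", names(lib$siteSets))
  names(lib$structures) <- paste0("lib_", names(lib$structures))
  libAct <- assignSyntheticActivities(lib$labels, intercept = sy$intercept,
                                      bonus = sy$bonus, noiseSD = sy$noiseSD,
                                      threshold = config$qsar$threshold,
                                      seed = config$seed + 1001L)
  library_ <- lapply(names(lib$siteSets), function(id)
    list(siteSets = lib$siteSets[[id]], structures = lib$structures[[id]]))
  names(library_) <- names(lib$siteSets)

  prepTab <- data.frame(id = ids, nSites = vapply(gen$siteSets, function(s)
    nrow(sites(s[[1]])), integer(1)), planted = gen$labels)
  utils::write.csv(prepTab, file.path(outDir, "prep_report.csv"),
                   row.names = FALSE)

  list(siteSets = gen$siteSets, structures = gen$structures,
       pIC50 = pIC50, library = library_,
       libraryObserved = stats::setNames(libAct$active,
                                         names(lib$siteSets)),
       fingerprints = NULL, planted = gen$labels)
}

# ---- SMILES-tier inputs ----------------------------------------------------

.pipelineSmilesInputs <- function(config, outDir) {
  if (is.null(config$input$compounds))
    stop("smiles mode requires input$compounds (a compound table path)")
  prepCfg <- do.call(prepConfig, config$prep)
  mset <- loadCompoundTable(config$input$compounds, config = prepCfg)
  mset <- prepareMolecules(mset, prepCfg)
  utils::write.csv(prepReport(mset), file.path(outDir, "prep_report.csv"),
                   row.names = FALSE)
  defs <- defaultFeatureDefinitions()
  siteSets <- perceiveSites(mset, defs)
  structures <- lapply(records(mset), function(r)
    lapply(r$conformers, function(cf) atomStructure(r, cf$confId)))
  pIC50 <- stats::setNames(
    vapply(records(mset), function(r) r$pIC50, numeric(1)),
    moleculeIds(mset))

  library_ <- NULL; libraryObserved <- NULL; fps <- NULL
  if (!is.null(config$input$library)) {
    lset <- loadCompoundTable(config$input$library, config = prepCfg)
    lset <- prepareMolecules(lset, prepCfg)
    libSites <- perceiveSites(lset, defs)
    library_ <- screenInput(lset, libSites)
    libP <- vapply(records(lset), function(r) r$pIC50, numeric(1))
    if (any(is.finite(libP)))
      libraryObserved <- stats::setNames(libP >= config$qsar$threshold,
                                         moleculeIds(lset))
    fps <- list(train = radialFingerprint(mset,
                                          radius = config$similarity$radius,
                                          nBits = config$similarity$nBits),
                library = radialFingerprint(lset,
                                            radius = config$similarity$radius,
                                            nBits = config$similarity$nBits))
  }
  list(siteSets = siteSets, structures = structures, pIC50 = pIC50,
       library = library_, libraryObserved = libraryObserved,
       fingerprints = fps, planted = NULL)
}

# ---- shared core -----------------------------------------------------------

.pipelineCore <- function(inputs, config, outDir) {
  qcfg <- config$qsar
  hcfg <- config$hypothesis
  threshold <- qcfg$threshold
  ids <- names(inputs$siteSets)
  pIC50 <- inputs$pIC50[ids]
  activeLab <- pIC50 >= threshold

  split <- makeSplit(ids, strategy = config$split$strategy,
                     seed = config$seed,
                     trainFraction = config$split$trainFraction)
  trainIds <- split$train; testIds <- split$test
  trainActives <- trainIds[activeLab[trainIds]]
  trainInactives <- trainIds[!activeLab[trainIds]]
  if (length(trainActives) < 2L)
    stop("fewer than 2 active training molecules")

  # hypotheses per requested k
  hyps <- list()
  for (k in hcfg$k) {
    hk <- enumerateCommonPharmacophores(
      inputs$siteSets[trainActives], k = k,
      minActiveFraction = hcfg$minActiveFraction,
      matchTolerance = hcfg$matchTolerance)
    hyps <- c(hyps, hk)
  }
  if (!length(hyps)) stop("no hypothesis survived enumeration")
  hyps <- scoreHypotheses(hyps, inputs$siteSets[trainActives],
                          inputs$siteSets[trainInactives],
                          structures = inputs$structures)
  hyps <- filterTopHypotheses(hyps, hcfg$survivalFraction)
  writeHypothesesJSON(hyps, file.path(outDir, "hypotheses.json"))
  hypTab <- data.frame(
    variant = vapply(hyps, variantCode, character(1)),
    k = vapply(hyps, function(h) length(h@siteTypes), integer(1)),
    reference = vapply(hyps, function(h) h@referenceLigandId, character(1)),
    nMatchingActives = vapply(hyps, function(h) h@nMatchingActives,
                              integer(1)),
    adjustedScore = vapply(hyps, adjustedScore, numeric(1)))
  utils::write.csv(hypTab, file.path(outDir, "hypothesis_summary.csv"),
                   row.names = FALSE)

  best <- hyps[[1L]]
  hypId <- paste0(best@variant, ".", best@referenceLigandId)

  # align training molecules and fit
  trainMatches <- lapply(trainIds, function(id)
    bestConformerMatch(inputs$siteSets[[id]], best, qcfg$minSites))
  names(trainMatches) <- trainIds
  matchedTrain <- trainIds[!vapply(trainMatches, is.null, logical(1))]
  posed <- lapply(matchedTrain, function(id) {
    m <- trainMatches[[id]]
    st <- inputs$structures[[id]][[m$confId]]
    list(coords = applyRigid(st$coords, m$rotation, m$translation),
         classes = st$classes, radii = st$radii)
  })
  names(posed) <- matchedTrain
  gridFrom <- which(matchedTrain %in% trainActives)
  desc <- buildOccupancyDescriptors(posed, gridFrom = gridFrom,
                                    spacing = qcfg$spacing,
                                    margin = qcfg$margin)
  model <- fitQSAR(desc, pIC50[matchedTrain], factors = qcfg$factors,
                   hypothesisId = hypId, threshold = threshold)
  stab <- estimateStability(model, desc$X, pIC50[matchedTrain],
                            rounds = qcfg$stabilityRounds,
                            holdoutFraction = qcfg$holdoutFraction,
                            seed = config$seed + 2L)
  model@stats$stability <- stab

  # test-set evaluation
  testStats <- NULL
  if (length(testIds) >= 3L) {
    preds <- vapply(testIds, function(id) {
      pr <- predictActivity(model, inputs$siteSets[[id]],
                            inputs$structures[[id]], best, qcfg$minSites)
      pr$predicted
    }, numeric(1))
    okPred <- is.finite(preds)
    if (sum(okPred) >= 3L) {
      testStats <- qsarTestStats(pIC50[testIds][okPred], preds[okPred])
      model@stats$RMSE <- testStats$RMSE
      model@stats$Q2 <- testStats$Q2
      model@stats$pearsonR <- testStats$pearsonR
    }
    predActive <- okPred & preds >= threshold  # non hits count as inactive
    testConf <- confusionCounts(predActive, activeLab[testIds])
    testConfStats <- confusionStats(testConf)
    utils::write.csv(
      data.frame(set = "test", t(testConf), t(unlist(testConfStats))),
      file.path(outDir, "test_confusion.csv"), row.names = FALSE)
  }
  writeModelJSON(model, file.path(outDir, "model.json"))
  st <- model@stats
  utils::write.csv(
    data.frame(hypothesis = hypId, SD = st$SD, R2 = st$R2, F = st$F,
               p = st$p, stability = st$stability,
               RMSE = st$RMSE %||% NA_real_, Q2 = st$Q2 %||% NA_real_,
               pearsonR = st$pearsonR %||% NA_real_),
    file.path(outDir, "model_stats.csv"), row.names = FALSE)
  writeCoefficientMap(exportCoefficientMap(model),
                      file.path(outDir, "coefficient_map.csv"))

  # external screening
  screen <- NULL; hitRate <- NULL; strat <- NULL
  if (!is.null(inputs$library)) {
    screen <- screenLibrary(inputs$library, model, best,
                            minSites = qcfg$minSites, threshold = threshold)
    writeScreenCSV(rankScreenResults(screen),
                   file.path(outDir, "screen.csv"))
    hitRate <- computeHitRate(screen)
    utils::write.csv(
      data.frame(hypothesis = hypId, n = nrow(screen),
                 hits = hitRate$hitCount,
                 hitRatePercent = hitRate$hitRatePercent),
      file.path(outDir, "hit_rates.csv"), row.names = FALSE)
    if (!is.null(inputs$libraryObserved)) {
      obs <- inputs$libraryObserved[screen$moleculeId]
      conf <- confusionCounts(screen$isHit, obs)
      utils::write.csv(
        data.frame(set = "library", t(conf),
                   t(unlist(confusionStats(conf)))),
        file.path(outDir, "library_confusion.csv"), row.names = FALSE)
      maxSim <- .maxSimilarityToTrain(inputs, screen$moleculeId, posed,
                                      model, best, qcfg$minSites, config)
      strat <- stratifyBySimilarity(
        data.frame(moleculeId = screen$moleculeId,
                   predicted = screen$isHit, observed = obs,
                   maxSimilarity = maxSim),
        bands = config$similarity$bands)
      utils::write.csv(strat$perBand,
                       file.path(outDir, "similarity_bands.csv"),
                       row.names = FALSE)
      utils::write.csv(strat$perRecord,
                       file.path(outDir, "similarity_report.csv"),
                       row.names = FALSE)
    }
  }

  manifest <- .writeManifest(config, outDir)
  invisible(list(hypotheses = hyps, model = model, testStats = testStats,
                 screen = screen, hitRate = hitRate,
                 stratification = strat, manifest = manifest,
                 outDir = outDir))
}

# Maximum similarity of each library compound to the training set: radial
# fingerprints when available (SMILES tier), otherwise occupancy-bit
# profiles of the hypothesis-posed structures on the model grid (geometry
# tier). Library compounds that cannot be posed get similarity 0.
.maxSimilarityToTrain <- function(inputs, libIds, posedTrain, model, hyp,
                                  minSites, config) {
  matchedTrain <- names(posedTrain)
  if (!is.null(inputs$fingerprints)) {
    M <- pairwiseSimilarityMatrix(
      inputs$fingerprints$library[libIds],
      inputs$fingerprints$train[matchedTrain])
    return(apply(M, 1L, max))
  }
  grid <- list(origin = model@gridOrigin, spacing = model@gridSpacing,
               dims = model@gridDims)
  trainProfiles <- lapply(posedTrain, .occupiedKeys, grid = grid)
  sims <- numeric(length(libIds))
  for (i in seq_along(libIds)) {
    entry <- inputs$library[[libIds[i]]]
    m <- bestConformerMatch(entry$siteSets, hyp, minSites)
    if (is.null(m)) {
      sims[i] <- 0
      next
    }
    st <- entry$structures[[m$confId]]
    keys <- .occupiedKeys(list(coords = applyRigid(st$coords, m$rotation,
                                                   m$translation),
                               classes = st$classes, radii = st$radii),
                          grid = grid)
    if (!length(keys)) {
      sims[i] <- 0
      next
    }
    best <- 0
    for (tp in trainProfiles) {
      u <- length(union(keys, tp))
      if (u > 0) best <- max(best, length(intersect(keys, tp)) / u)
    }
    sims[i] <- best
  }
  sims
}

.writeManifest <- function(config, outDir) {
  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  sums <- tools::md5sum(file.path(outDir, files))
  manifest <- list(package = "PharmSafe3D",
                   version = as.character(utils::packageVersion("PharmSafe3D")),
                   seed = config$seed, config = config,
                   files = data.frame(file = files, md5 = unname(sums)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
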
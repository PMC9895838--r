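#' @include sufficiency.R
NULL

#' Default pipeline configuration
#'
#' Every analysis parameter appears explicitly with its standard value: delays
#' 0-600 ms, 15 log-spaced ridge penalties between 1e2 and 1e8, learning
#' curves starting at 10 trials growing by 1 with 10 bootstrap replicates,
#' 1-15 Hz band, 128 Hz sampling.
#'
#' @return Nested list; see the fields of the returned value.
#' @export
defaultRunConfig <- function() {
  list(
    dataset = list(
      source = "synthetic",
      nTrials = 40L,
      meanDuration = 2,
      samplingRate = 128,
      channels = 16L,
      snrDb = 10,
      noiseSpectrum = "pink",
      design = list(type = "repeated-test", nTestStimuli = 5L, nRepeats = 5L)),
    featureSets = list("full"),
    ridge = list(alphas = defaultAlphaGrid(), nFolds = 5L,
                 delaySpan = c(0, 0.6)),
    sufficiency = list(startSize = 10L, step = 1L, nBoot = 10L,
                       smoothWindow = 5L, boundaryMargin = 0.05,
                       stabilityThreshold = 0.9),
    preprocessing = list(band = c(1, 15), notch = 60, targetRate = 128),
    seed = 1L,
    outDir = "mtrfknee-run")
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to [defaultRunConfig()].
#'
#' @param path Path to a YAML file.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  mergeConfig(defaultRunConfig(), user)
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

featureSetRows <- function(label) {
  switch(label,
    full = c("envelope", "pitch", phonologicalFeatureNames()),
    envelope = "envelope",
    pitch = "pitch",
    `phonological-14` = phonologicalFeatureNames(),
    stop("unknown feature set label: ", label))
}

featureSetConfig <- function(label) {
  switch(label,
    full = c("envelope", "pitch", "phonological-14"),
    envelope = "envelope",
    pitch = "pitch",
    `phonological-14` = "phonological-14")
}

subsetTrialFeatures <- function(trials, rows) {
  newTrials <- lapply(trials@trials, function(tr) {
    tr$features <- FeatureMatrix(
      tr$features@values[rows, , drop = FALSE],
      samplingRate(tr$features))
    tr
  })
  new("TrialSet", trials = newTrials, samplingRate = trials@samplingRate,
      repeatGroups = trials@repeatGroups)
}

#' Run the full sufficiency pipeline from a configuration
#'
#' Executes generate (or load) -> alpha selection -> learning curve -> knee ->
#' weight stability for every requested feature set, writing a tidy replicate
#' CSV, a JSON summary, and a run manifest (config echo, seed, MD5 content
#' hashes of every artifact). Re-running with an identical configuration and
#' seed reproduces the summary byte for byte.
#'
#' @param config Configuration list (see [defaultRunConfig()]) or the path to
#'   a YAML file.
#' @param outDir Output directory; overrides `config$outDir` when given.
#' @return The manifest, invisibly (a list; also written as `manifest.json`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- mergeConfig(defaultRunConfig(), config)
  if (!is.null(outDir)) config$outDir <- outDir
  validateRunConfig(config)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  ds <- config$dataset
  stage <- "generate dataset"
  manifest <- list(config = config, seed = seed, artifacts = list(),
                   stagesCompleted = character())
  result <- tryCatch({
    if (identical(ds$source, "synthetic")) {
      allFeatures <- c("envelope", "pitch", "phonological-14")
      trf <- makeGroundTruthTrf(
        c("envelope", "pitch", phonologicalFeatureNames()),
        ds$channels, ds$samplingRate, seed = deriveSeed(seed, "trf"))
      stims <- simulateStimulus(ds$nTrials, ds$meanDuration, ds$samplingRate,
                                allFeatures, seed = deriveSeed(seed, "stim"))
      noise <- NoiseSpec(ds$snrDb, ds$noiseSpectrum)
      eeg <- simulateEeg(trf, stims, noise, seed = deriveSeed(seed, "eeg"))
      trials <- assembleTrialSet(stims, eeg, ds$design,
                                 seed = deriveSeed(seed, "assemble"),
                                 trf = trf, noise = noise)
    } else {
      trials <- readDataset(ds$containerPath)
    }
    dsDir <- file.path(config$outDir, "dataset")
    writeDataset(trials, dsDir,
                 meta = list(seed = seed, generator = ds))
    manifest$datasetHash <- datasetHash(dsDir)
    manifest$stagesCompleted <- c(manifest$stagesCompleted, stage)

    suff <- config$sufficiency
    summary <- list(datasetHash = manifest$datasetHash, seed = seed,
                    featureSets = list())
    allRows <- list()
    for (label in unlist(config$featureSets)) {
      stage <- paste("feature set", label)
      sub <- subsetTrialFeatures(trials, featureSetRows(label))
      rcfg <- new("RidgeConfig",
                  alphas = as.numeric(unlist(config$ridge$alphas)),
                  nFolds = as.integer(config$ridge$nFolds),
                  delaySpan = as.numeric(unlist(config$ridge$delaySpan)))
      sel <- selectAlpha(sub, rcfg, seed = deriveSeed(seed, "alpha"))
      curve <- learningCurve(sub, sel$alpha,
                             startSize = suff$startSize, step = suff$step,
                             nBoot = suff$nBoot,
                             seed = deriveSeed(seed, paste0("curve-", label)),
                             delaySpan = rcfg@delaySpan)
      knee <- tryCatch(
        kneePoint(curve, smoothWindow = suff$smoothWindow,
                  boundaryMargin = suff$boundaryMargin),
        error = function(e) invalidKnee(as.numeric(curveSizes(curve)),
                                        conditionMessage(e),
                                        curve@secondsPerTrial))
      stab <- weightStability(curve, threshold = suff$stabilityThreshold)
      m <- curveMean(curve)
      summary$featureSets[[label]] <- list(
        alpha = sel$alpha,
        kneeTrials = kneeSize(knee),
        kneeSeconds = kneeSeconds(knee),
        kneeValid = kneeValid(knee),
        kneeReason = knee@reason,
        finalMean = m[length(m)],
        finalSE = curveSE(curve)[length(m)],
        stabilizationSize = stabilizationSize(stab),
        adjacentR = adjacentR(stab))
      allRows[[label]] <- learningCurveTable(curve, subject = "S01",
                                             label = label)
      manifest$stagesCompleted <- c(manifest$stagesCompleted, stage)
    }
    stage <- "write outputs"
    curvesPath <- file.path(config$outDir, "learning_curves.csv")
    utils::write.csv(do.call(rbind, allRows), curvesPath, row.names = FALSE)
    summaryPath <- file.path(config$outDir, "summary.json")
    jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    manifest$artifacts <- list(
      dataset = dsDir,
      learning_curves = curvesPath,
      summary = summaryPath)
    manifest$hashes <- as.list(tools::md5sum(c(curvesPath, summaryPath)))
    manifest$stagesCompleted <- c(manifest$stagesCompleted, stage)
    manifest$failedStage <- NULL
    manifest
  }, error = function(e) {
    manifest$failedStage <- stage
    manifest$error <- conditionMessage(e)
    manifestPath <- file.path(config$outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    stop("pipeline stage failed [", stage, "]: ", conditionMessage(e),
         " (partial outputs flagged in ", manifestPath, ")")
  })
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(result, manifestPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(result)
}

validateRunConfig <- function(config) {
  fs <- unlist(config$featureSets)
  if (!length(fs)) stop("featureSets must be nonempty")
  for (label in fs) featureSetRows(label)
  if (!identical(config$dataset$source, "synthetic")) {
    cp <- config$dataset$containerPath
    if (is.null(cp) || !dir.exists(cp))
      stop("dataset container not found: ",
           if (is.null(cp)) "<missing containerPath>" else cp)
  }
  invisible(TRUE)
}

datasetHash <- function(dsDir) {
  files <- sort(list.files(dsDir, full.names = TRUE))
  paste(tools::md5sum(files), collapse = "") |> charToRaw() |> md5raw()
}

md5raw <- function(raw) {
  tf <- tempfile()
  writeBin(raw, tf)
  on.exit(unlink(tf))
  as.character(tools::md5sum(tf))
}

#' Compare knee points and final scores across feature-set runs
#'
#' @param manifests Character vector of `manifest.json` paths (>= 2), or a
#'   list of manifest objects as returned by [runPipeline()]. All runs must
#'   share the same dataset hash; comparing curves across different datasets
#'   is undefined and rejected.
#' @return Data frame with one row per feature-set label: knee in trials and
#'   seconds, final mean score, and its bootstrap SE. No inferential
#'   statistics are computed.
#' @export
compareFeatureModels <- function(manifests) {
  if (length(manifests) < 2L) stop("need at least two run manifests")
  readOne <- function(m) {
    if (is.character(m)) {
      man <- jsonlite::read_json(m, simplifyVector = FALSE)
      sm <- jsonlite::read_json(file.path(dirname(m), "summary.json"),
                                simplifyVector = FALSE)
    } else {
      man <- m
      sm <- jsonlite::read_json(man$artifacts$summary,
                                simplifyVector = FALSE)
    }
    list(man = man, sm = sm)
  }
  runs <- lapply(manifests, readOne)
  hashes <- vapply(runs, function(r) r$man$datasetHash, character(1))
  if (length(unique(hashes)) != 1L)
    stop("manifests come from different datasets (dataset hash mismatch); ",
         "the comparison is undefined")
  rows <- list()
  for (r in runs) {
    for (label in names(r$sm$featureSets)) {
      fsum <- r$sm$featureSets[[label]]
      rows[[length(rows) + 1L]] <- data.frame(
        featureSet = label,
        kneeTrials = nullToNa(fsum$kneeTrials),
        kneeSeconds = nullToNa(fsum$kneeSeconds),
        finalMean = fsum$finalMean,
        finalSE = fsum$finalSE,
        datasetHash = r$man$datasetHash,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

nullToNa <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
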
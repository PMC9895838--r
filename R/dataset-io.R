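#' @include synthdata.R
NULL

#' Write a TrialSet to a plain-text dataset container
#'
#' One directory per dataset: a `meta.json` sidecar (sampling rate, trial ids,
#' roles, feature and channel names, repeat groups, plus any generator
#' metadata) and per-trial CSV matrices `features_<id>.csv` /
#' `eeg_<id>.csv`. Deterministic input yields a byte-identical container.
#'
#' @param trials A [TrialSet-class].
#' @param dir Output directory (created; existing trial files overwritten).
#' @param meta Optional list of extra metadata stored in the sidecar (e.g.
#'   the generator configuration and seed).
#' @return `dir`, invisibly.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(trials, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(trials@trials, function(tr) tr$id, character(1))
  roles <- vapply(trials@trials, function(tr) tr$role, character(1))
  sidecar <- list(
    samplingRate = trials@samplingRate,
    trialIds = ids,
    roles = roles,
    featureNames = featureNames(trials@trials[[1L]]$features),
    channelNames = channelNames(trials@trials[[1L]]$eeg),
    repeatGroups = trials@repeatGroups,
    meta = meta)
  jsonlite::write_json(sidecar, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tr in trials@trials) {
    utils::write.csv(format(tr$features@values, digits = 17, trim = TRUE),
                     file.path(dir, paste0("features_", tr$id, ".csv")),
                     row.names = TRUE)
    utils::write.csv(format(tr$eeg@values, digits = 17, trim = TRUE),
                     file.path(dir, paste0("eeg_", tr$id, ".csv")),
                     row.names = TRUE)
  }
  invisible(dir)
}

#' Read a TrialSet from a dataset container
#'
#' @param dir Directory written by [writeDataset()].
#' @return A [TrialSet-class].
#' @export
readDataset <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("no meta.json in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  rate <- meta$samplingRate
  readMat <- function(path) {
    tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "numeric"
    colnames(m) <- NULL
    m
  }
  trials <- lapply(seq_along(meta$trialIds), function(i) {
    id <- meta$trialIds[i]
    fv <- readMat(file.path(dir, paste0("features_", id, ".csv")))
    ev <- readMat(file.path(dir, paste0("eeg_", id, ".csv")))
    list(id = id, features = FeatureMatrix(fv, rate),
         eeg = EEGRecording(ev, rate), role = meta$roles[i])
  })
  rg <- meta$repeatGroups
  if (is.null(rg) || !length(rg)) rg <- list()
  else rg <- lapply(rg, unlist)
  new("TrialSet", trials = trials, samplingRate = rate, repeatGroups = rg)
}

#' Write a fitted TRF model to a plain-text container
#'
#' A directory holding `model.json` (delay grid, alpha, feature and channel
#' names, training duration) and `weights.csv` (rows = feature x delay,
#' columns = channels).
#'
#' @param model A [TRFModel-class].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeTrfModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W <- weights(model)
  d <- dim(W)
  flat <- matrix(W, d[1L] * d[2L], d[3L])
  colnames(flat) <- channelNames(model)
  rownames(flat) <- paste(rep(featureNames(model), times = d[2L]),
                          rep(seq_len(d[2L]) - 1L, each = d[1L]), sep = "_lag")
  jsonlite::write_json(list(
    delayGrid = delayGrid(model), alpha = alphaUsed(model),
    featureNames = featureNames(model), channelNames = channelNames(model),
    samplingRate = samplingRate(model),
    trainingSeconds = trainingSeconds(model)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(format(flat, digits = 17, trim = TRUE),
                   file.path(dir, "weights.csv"), row.names = TRUE)
  invisible(dir)
}

#' Read a fitted TRF model written by [writeTrfModel()]
#'
#' @param dir Model container directory.
#' @return A [TRFModel-class].
#' @export
readTrfModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "weights.csv"), row.names = 1L,
                         check.names = FALSE)
  flat <- as.matrix(tab)
  storage.mode(flat) <- "numeric"
  nF <- length(meta$featureNames)
  nd <- length(meta$delayGrid)
  W <- array(flat, dim = c(nF, nd, ncol(flat)),
             dimnames = list(meta$featureNames, NULL, meta$channelNames))
  new("TRFModel", weights = W, delayGrid = meta$delayGrid,
      featureNames = meta$featureNames, samplingRate = meta$samplingRate,
      alpha = meta$alpha, trainingSeconds = meta$trainingSeconds)
}
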
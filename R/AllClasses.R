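#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- FeatureMatrix

#' FeatureMatrix: time-aligned stimulus representation
#'
#' Named feature rows by time samples at a stated sampling rate. Houses the
#' stimulus term of the encoding model: each row is one feature stream (for
#' example the acoustic envelope, the pitch track, or one binary phonological
#' onset row).
#'
#' @slot values Numeric matrix, features by time samples. Row names are the
#'   feature labels.
#' @slot samplingRate Sampling rate in Hz.
#'
#' @seealso [FeatureMatrix()], [extractEnvelope()], [phonologicalOnsetMatrix()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", samplingRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (is.null(rownames(object@values)))
      msg <- c(msg, "values must have feature names as row names")
    else if (anyDuplicated(rownames(object@values)))
      msg <- c(msg, "feature names must be unique")
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be numeric")
    if (length(msg)) msg else TRUE
  })

#' Construct a FeatureMatrix
#'
#' @param values Numeric matrix, features by time samples (a vector is treated
#'   as a single row).
#' @param samplingRate Sampling rate in Hz.
#' @param featureNames Optional character vector of row labels; defaults to the
#'   row names of `values`.
#' @return A [FeatureMatrix-class] object.
#' @examples
#' fm <- FeatureMatrix(matrix(rnorm(256), 1), 128, "envelope")
#' featureNames(fm)
#' @export
FeatureMatrix <- function(values, samplingRate, featureNames = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.null(featureNames)) {
    if (length(featureNames) != nrow(values))
      stop("featureNames length (", length(featureNames),
           ") does not match row count (", nrow(values), ")")
    rownames(values) <- featureNames
  }
  new("FeatureMatrix", values = values, samplingRate = as.numeric(samplingRate))
}

# ---------------------------------------------------------------- EEGRecording

#' EEGRecording: multichannel neural time series
#'
#' Channels by time samples at a stated rate, with channel names. Houses the
#' measured (or simulated, or predicted) EEG in the encoding model.
#'
#' @slot values Numeric matrix, channels by time samples. Row names are channel
#'   labels.
#' @slot samplingRate Sampling rate in Hz.
#' @export
setClass("EEGRecording",
  representation(values = "matrix", samplingRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
      msg <- c(msg, "samplingRate must be a single positive number")
    if (is.null(rownames(object@values)))
      msg <- c(msg, "values must have channel names as row names")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct an EEGRecording
#'
#' @param values Numeric matrix, channels by time samples (a vector is treated
#'   as one channel).
#' @param samplingRate Sampling rate in Hz.
#' @param channelNames Optional channel labels; default `chan01`, `chan02`, ...
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(values, samplingRate, channelNames = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (is.null(channelNames)) {
    channelNames <- rownames(values)
    if (is.null(channelNames))
      channelNames <- sprintf("chan%02d", seq_len(nrow(values)))
  }
  if (length(channelNames) != nrow(values))
    stop("channelNames length does not match channel count")
  rownames(values) <- channelNames
  new("EEGRecording", values = values, samplingRate = as.numeric(samplingRate))
}

# ------------------------------------------------------------------------- TRF

#' TRF: temporal receptive field weight array
#'
#' Base class for receptive-field weights indexed (feature, delay, channel),
#' with the delay grid in seconds. [GroundTruthTRF-class] adds generator
#' semantics; [TRFModel-class] adds the fit metadata.
#'
#' @slot weights Numeric array, feature by delay by channel.
#' @slot delayGrid Delays in seconds, ascending, starting at 0, spaced at the
#'   EEG sampling interval.
#' @slot featureNames Ordered feature labels.
#' @slot samplingRate Sampling rate (Hz) the delay grid is defined on.
#' @export
setClass("TRF",
  representation(weights = "array", delayGrid = "numeric",
                 featureNames = "character", samplingRate = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@weights)
    if (length(d) != 3L)
      msg <- c(msg, "weights must be a 3-d array (feature x delay x channel)")
    else {
      if (d[1L] != length(object@featureNames))
        msg <- c(msg, "weights feature dimension does not match featureNames")
      if (d[2L] != length(object@delayGrid))
        msg <- c(msg, "weights delay dimension does not match delayGrid")
    }
    if (any(!is.finite(object@weights)))
      msg <- c(msg, "weights must be finite")
    if (length(object@delayGrid)) {
      if (abs(object@delayGrid[1L]) > 1e-12)
        msg <- c(msg, "delayGrid must start at 0")
      if (length(object@delayGrid) > 1L) {
        dd <- diff(object@delayGrid)
        if (any(dd <= 0) || diff(range(dd)) > 1e-9)
          msg <- c(msg, "delayGrid must be ascending and uniformly spaced")
        if (abs(dd[1L] - 1 / object@samplingRate) > 1e-9)
          msg <- c(msg, "delayGrid spacing must equal 1/samplingRate")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' GroundTruthTRF: generative receptive field for simulation
#'
#' The receptive field the synthetic-data generator convolves with stimulus
#' features. Weights are zero outside the 0-0.6 s delay window by
#' construction.
#'
#' @seealso [makeGroundTruthTrf()]
#' @export
setClass("GroundTruthTRF", contains = "TRF")

#' TRFModel: fitted encoding-model weights
#'
#' @slot alpha Ridge regularization value used for the fit.
#' @slot trainingSeconds Total duration of the training data, seconds.
#' @seealso [ridgeFit()], [fitTrf()]
#' @export
setClass("TRFModel", contains = "TRF",
  representation(alpha = "numeric", trainingSeconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@alpha) != 1L || object@alpha < 0)
      msg <- c(msg, "alpha must be a single non-negative number")
    if (length(object@delayGrid) &&
        max(object@delayGrid) > 0.6 + 1e-9)
      msg <- c(msg, "delayGrid must lie within [0, 0.6] s")
    if (length(msg)) msg else TRUE
  })

# ------------------------------------------------------------------- NoiseSpec

#' NoiseSpec: additive-noise description for the EEG simulator
#'
#' @slot snrDb Target per-channel signal-to-noise ratio in dB; `Inf` yields the
#'   exact noiseless convolution.
#' @slot spectrum Either `"white"` or `"pink"` (1/f).
#' @slot perChannelScale Optional multiplicative factors applied to the noise of
#'   each channel after SNR scaling (length 0 = none).
#' @export
setClass("NoiseSpec",
  representation(snrDb = "numeric", spectrum = "character",
                 perChannelScale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@snrDb) != 1L || is.na(object@snrDb))
      msg <- c(msg, "snrDb must be a single number (possibly Inf)")
    if (!object@spectrum %in% c("white", "pink"))
      msg <- c(msg, "spectrum must be 'white' or 'pink'")
    if (length(msg)) msg else TRUE
  })

#' Construct a NoiseSpec
#'
#' @param snrDb Target SNR in dB (`Inf` = noiseless).
#' @param spectrum `"pink"` (default, EEG-like 1/f) or `"white"`.
#' @param perChannelScale Optional per-channel noise multipliers.
#' @return A [NoiseSpec-class] object.
#' @export
NoiseSpec <- function(snrDb = Inf, spectrum = c("pink", "white"),
                      perChannelScale = numeric()) {
  spectrum <- match.arg(spectrum)
  new("NoiseSpec", snrDb = as.numeric(snrDb), spectrum = spectrum,
      perChannelScale = as.numeric(perChannelScale))
}

# -------------------------------------------------------------------- TrialSet

#' TrialSet: trials with train/test roles and repeat structure
#'
#' An ordered collection of trials, each pairing a [FeatureMatrix-class] with an
#' [EEGRecording-class] under a role (`train`, `test`, or `test-repeat`), plus
#' the grouping of repeated presentations of the same test stimulus.
#'
#' @slot trials List of trials; each element is a list with components `id`,
#'   `features`, `eeg`, `role`.
#' @slot samplingRate Common sampling rate in Hz.
#' @slot repeatGroups Named list: test stimulus id -> trial ids of its repeats.
#' @seealso [assembleTrialSet()]
#' @export
setClass("TrialSet",
  representation(trials = "list", samplingRate = "numeric",
                 repeatGroups = "list"),
  validity = function(object) {
    msg <- character()
    ids <- vapply(object@trials, function(tr) tr$id, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "trial ids must be unique")
    for (tr in object@trials) {
      if (!all(c("id", "features", "eeg", "role") %in% names(tr))) {
        msg <- c(msg, "each trial needs id, features, eeg, role")
        break
      }
      if (!tr$role %in% c("train", "test", "test-repeat")) {
        msg <- c(msg, sprintf("trial '%s': unknown role '%s'", tr$id, tr$role))
        break
      }
      if (ncol(tr$features@values) != ncol(tr$eeg@values)) {
        msg <- c(msg, sprintf(
          "trial '%s': features and EEG sample counts differ", tr$id))
        break
      }
      if (abs(tr$features@samplingRate - object@samplingRate) > 1e-9 ||
          abs(tr$eeg@samplingRate - object@samplingRate) > 1e-9) {
        msg <- c(msg, sprintf("trial '%s': sampling rate mismatch", tr$id))
        break
      }
    }
    for (g in names(object@repeatGroups)) {
      members <- object@repeatGroups[[g]]
      idx <- match(members, ids)
      if (any(is.na(idx))) {
        msg <- c(msg, sprintf("repeat group '%s' references unknown trials", g))
        next
      }
      roles <- vapply(object@trials[idx], function(tr) tr$role, character(1))
      if (!all(roles == "test-repeat"))
        msg <- c(msg, sprintf(
          "repeat group '%s' members must all have role 'test-repeat'", g))
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------- LaggedDesign

#' LaggedDesign: time-lagged stimulus design matrix
#'
#' Rows are time samples; columns are (feature, delay) pairs so that the column
#' for feature f at delay tau holds the feature stream shifted by tau (zero
#' before trial onset).
#'
#' @slot matrix Numeric matrix, time samples by (features x delays).
#' @slot delayGrid Delays in seconds, ascending from 0, uniformly spaced.
#' @slot featureNames Ordered feature labels.
#' @slot samplingRate Sampling rate in Hz.
#' @seealso [buildLaggedDesign()]
#' @export
setClass("LaggedDesign",
  representation(matrix = "matrix", delayGrid = "numeric",
                 featureNames = "character", samplingRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@matrix) !=
        length(object@featureNames) * length(object@delayGrid))
      msg <- c(msg, "column count must equal n_features * n_delays")
    if (length(object@delayGrid) && abs(object@delayGrid[1L]) > 1e-12)
      msg <- c(msg, "delayGrid must start at 0")
    if (length(msg)) msg else TRUE
  })

# ----------------------------------------------------------------- RidgeConfig

#' RidgeConfig: regularization search settings
#'
#' @slot alphas Candidate ridge penalties, positive and ascending.
#' @slot nFolds Number of cross-validation folds (>= 2).
#' @slot delaySpan Two numbers, the delay window in seconds (default 0 to 0.6).
#' @export
setClass("RidgeConfig",
  representation(alphas = "numeric", nFolds = "integer", delaySpan = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!length(object@alphas))
      msg <- c(msg, "alpha grid must be non-empty")
    else if (any(object@alphas <= 0) || is.unsorted(object@alphas, strictly = TRUE))
      msg <- c(msg, "alphas must be positive and strictly ascending")
    if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
    if (length(object@delaySpan) != 2L || object@delaySpan[1L] != 0 ||
        object@delaySpan[2L] <= 0)
      msg <- c(msg, "delaySpan must be c(0, d_max) with d_max > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a RidgeConfig
#'
#' Defaults follow the standard speech-mTRF recipe: 15 log-spaced penalties
#' between 1e2 and 1e8, and delays 0-600 ms.
#'
#' @param alphas Candidate ridge penalties (positive, ascending).
#' @param nFolds Cross-validation folds.
#' @param delaySpan Delay window `c(0, d_max)` in seconds.
#' @return A [RidgeConfig-class] object.
#' @export
RidgeConfig <- function(alphas = defaultAlphaGrid(), nFolds = 5L,
                        delaySpan = c(0, 0.6)) {
  new("RidgeConfig", alphas = as.numeric(alphas), nFolds = as.integer(nFolds),
      delaySpan = as.numeric(delaySpan))
}

# --------------------------------------------------------------- LearningCurve

#' LearningCurve: bootstrap model performance vs training-set size
#'
#' For each training-set size, the channel-averaged test-set correlations of
#' `nBoot` bootstrap refits, plus (optionally) the model sequence of the first
#' replicate for weight-stability analysis.
#'
#' @slot sizes Ascending training-set sizes, in trials/chunks.
#' @slot secondsPerTrial Mean trial duration (s), converting sizes to seconds.
#' @slot scores Numeric matrix, sizes by replicates.
#' @slot nBoot Replicates per size.
#' @slot models List of [TRFModel-class] objects for the designated replicate
#'   (possibly empty).
#' @slot alpha Ridge penalty shared by every fit.
#' @seealso [learningCurve()], [kneePoint()], [weightStability()]
#' @export
setClass("LearningCurve",
  representation(sizes = "integer", secondsPerTrial = "numeric",
                 scores = "matrix", nBoot = "integer", models = "list",
                 alpha = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@sizes, strictly = TRUE))
      msg <- c(msg, "sizes must be strictly ascending")
    if (nrow(object@scores) != length(object@sizes))
      msg <- c(msg, "scores rows must match sizes")
    if (ncol(object@scores) != object@nBoot)
      msg <- c(msg, "scores columns must equal nBoot")
    if (any(!is.finite(rowMeans(object@scores))))
      msg <- c(msg, "per-size means must be finite")
    if (length(object@models) &&
        length(object@models) != length(object@sizes))
      msg <- c(msg, "models, when kept, must have one entry per size")
    if (length(msg)) msg else TRUE
  })

# ------------------------------------------------------------------ KneeResult

#' KneeResult: curvature-based knee of a learning curve
#'
#' @slot kneeSize Size at maximal curvature magnitude (NA when invalid).
#' @slot kneeSeconds Knee converted to seconds of training data (NA if the
#'   curve has no seconds equivalent or the knee is invalid).
#' @slot sizes The size grid the curvature was evaluated on.
#' @slot curvature Curvature values along the grid (NA at undefined points).
#' @slot valid Whether a usable knee was found.
#' @slot reason Explanation when invalid ("" when valid).
#' @seealso [kneePoint()], [grandAverageKnee()]
#' @export
setClass("KneeResult",
  representation(kneeSize = "numeric", kneeSeconds = "numeric",
                 sizes = "numeric", curvature = "numeric", valid = "logical",
                 reason = "character"),
  validity = function(object) {
    msg <- character()
    if (object@valid) {
      if (is.na(object@kneeSize) ||
          object@kneeSize < min(object@sizes) - 1e-9 ||
          object@kneeSize > max(object@sizes) + 1e-9)
        msg <- c(msg, "valid knee must lie within the size grid")
    }
    if (length(msg)) msg else TRUE
  })

# -------------------------------------------------------------- StabilityCurve

#' StabilityCurve: adjacent-weight correlation vs training-set size
#'
#' @slot sizes Sizes from the second fitted size onward.
#' @slot adjacentR Pearson correlation between the flattened weights of
#'   consecutive sizes; length equals `length(sizes)`.
#' @slot stabilizationSize First size after which every subsequent correlation
#'   stays at or above the threshold (NA if never).
#' @slot threshold The stability threshold used.
#' @seealso [weightStability()]
#' @export
setClass("StabilityCurve",
  representation(sizes = "numeric", adjacentR = "numeric",
                 stabilizationSize = "numeric", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@adjacentR) != length(object@sizes))
      msg <- c(msg, "adjacentR length must match sizes")
    if (any(abs(object@adjacentR) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

# ------------------------------------------------------------------- accessors

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "FeatureMatrix", function(x) x@samplingRate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TRF", function(x) x@samplingRate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@samplingRate)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "LaggedDesign", function(x) x@samplingRate)

#' @rdname featureNames
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) rownames(x@values))
#' @rdname featureNames
#' @export
setMethod("featureNames", "TRF", function(x) x@featureNames)
#' @rdname featureNames
#' @export
setMethod("featureNames", "LaggedDesign", function(x) x@featureNames)

#' @rdname channelNames
#' @export
setMethod("channelNames", "EEGRecording", function(x) rownames(x@values))
#' @rdname channelNames
#' @export
setMethod("channelNames", "TRF", function(x) {
  cn <- dimnames(x@weights)[[3L]]
  if (is.null(cn)) sprintf("chan%02d", seq_len(dim(x@weights)[3L])) else cn
})

#' @rdname nChannels
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@values))
#' @rdname nChannels
#' @export
setMethod("nChannels", "TRF", function(x) dim(x@weights)[3L])

#' @rdname nSamples
#' @export
setMethod("nSamples", "FeatureMatrix", function(x) ncol(x@values))
#' @rdname nSamples
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@values))

#' @rdname delayGrid
#' @export
setMethod("delayGrid", "TRF", function(x) x@delayGrid)
#' @rdname delayGrid
#' @export
setMethod("delayGrid", "LaggedDesign", function(x) x@delayGrid)

#' @rdname alphaUsed
#' @export
setMethod("alphaUsed", "TRFModel", function(x) x@alpha)

#' @rdname trainingSeconds
#' @export
setMethod("trainingSeconds", "TRFModel", function(x) x@trainingSeconds)

#' Receptive-field weights of a TRF object
#'
#' @param object A [TRF-class] object.
#' @param ... Ignored.
#' @return Numeric array, feature by delay by channel.
#' @export
setMethod("weights", "TRF", function(object, ...) object@weights)

#' @rdname trialRoles
#' @export
setMethod("trialRoles", "TrialSet", function(x) {
  roles <- vapply(x@trials, function(tr) tr$role, character(1))
  names(roles) <- vapply(x@trials, function(tr) tr$id, character(1))
  roles
})

#' @rdname repeatGroups
#' @export
setMethod("repeatGroups", "TrialSet", function(x) x@repeatGroups)

#' Number of trials in a TrialSet
#' @param x A [TrialSet-class] object.
#' @return Integer trial count.
#' @export
setMethod("length", "TrialSet", function(x) length(x@trials))

#' Extract one trial from a TrialSet
#'
#' @param x A [TrialSet-class] object.
#' @param i Trial index or trial id.
#' @return A list with components `id`, `features`, `eeg`, `role`.
#' @export
setMethod("[[", "TrialSet", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@trials, function(tr) tr$id, character(1))
    i <- match(i, ids)
    if (is.na(i)) stop("no trial with that id")
  }
  x@trials[[i]]
})

#' @rdname curveSizes
#' @export
setMethod("curveSizes", "LearningCurve", function(x) x@sizes)
#' @rdname curveSeconds
#' @export
setMethod("curveSeconds", "LearningCurve",
          function(x) x@sizes * x@secondsPerTrial)
#' @rdname replicateScores
#' @export
setMethod("replicateScores", "LearningCurve", function(x) x@scores)
#' @rdname curveMean
#' @export
setMethod("curveMean", "LearningCurve", function(x) rowMeans(x@scores))
#' @rdname curveSE
#' @export
setMethod("curveSE", "LearningCurve", function(x)
  apply(x@scores, 1L, stats::sd) / sqrt(ncol(x@scores)))
#' @rdname refModels
#' @export
setMethod("refModels", "LearningCurve", function(x) x@models)

#' @rdname kneeSize
#' @export
setMethod("kneeSize", "KneeResult", function(x) x@kneeSize)
#' @rdname kneeSeconds
#' @export
setMethod("kneeSeconds", "KneeResult", function(x) x@kneeSeconds)
#' @rdname kneeValid
#' @export
setMethod("kneeValid", "KneeResult", function(x) x@valid)
#' @rdname curvatureValues
#' @export
setMethod("curvatureValues", "KneeResult", function(x) x@curvature)

#' @rdname adjacentR
#' @export
setMethod("adjacentR", "StabilityCurve", function(x) x@adjacentR)
#' @rdname stabilizationSize
#' @export
setMethod("stabilizationSize", "StabilityCurve", function(x) x@stabilizationSize)

# ------------------------------------------------------------------------ show

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d feature(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(object@values), ncol(object@values), object@samplingRate,
              ncol(object@values) / object@samplingRate))
  cat("  features:", paste(utils::head(rownames(object@values), 6L),
                           collapse = ", "),
      if (nrow(object@values) > 6L) "..." else "", "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(object@values), ncol(object@values), object@samplingRate,
              ncol(object@values) / object@samplingRate))
})

setMethod("show", "TRF", function(object) {
  d <- dim(object@weights)
  cat(sprintf("%s: %d feature(s) x %d delays x %d channel(s)\n",
              class(object), d[1L], d[2L], d[3L]))
  cat(sprintf("  delays: %.0f-%.0f ms @ %g Hz\n",
              1000 * min(object@delayGrid), 1000 * max(object@delayGrid),
              object@samplingRate))
  if (is(object, "TRFModel"))
    cat(sprintf("  alpha: %g, training: %.1f s\n", object@alpha,
                object@trainingSeconds))
})

setMethod("show", "TrialSet", function(object) {
  roles <- vapply(object@trials, function(tr) tr$role, character(1))
  cat(sprintf("TrialSet: %d trials @ %g Hz (%d train, %d test, %d test-repeat)\n",
              length(object@trials), object@samplingRate,
              sum(roles == "train"), sum(roles == "test"),
              sum(roles == "test-repeat")))
  if (length(object@repeatGroups))
    cat(sprintf("  %d repeat group(s), %s presentations each\n",
                length(object@repeatGroups),
                paste(unique(lengths(object@repeatGroups)), collapse = "/")))
})

setMethod("show", "LearningCurve", function(object) {
  m <- rowMeans(object@scores)
  cat(sprintf(
    "LearningCurve: sizes %d-%d (%d points), %d bootstrap replicates\n",
    min(object@sizes), max(object@sizes), length(object@sizes), object@nBoot))
  cat(sprintf("  mean r: %.3f (first) -> %.3f (final); alpha = %g\n",
              m[1L], m[length(m)], object@alpha))
})

setMethod("show", "KneeResult", function(object) {
  if (object@valid)
    cat(sprintf("KneeResult: knee at size %g%s\n", object@kneeSize,
                if (!is.na(object@kneeSeconds))
                  sprintf(" (%.1f s of training data)", object@kneeSeconds)
                else ""))
  else
    cat(sprintf("KneeResult: no valid knee (%s)\n", object@reason))
})

setMethod("show", "StabilityCurve", function(object) {
  cat(sprintf("StabilityCurve: %d adjacent-size correlations, threshold %.2f\n",
              length(object@adjacentR), object@threshold))
  cat(sprintf("  stabilization size: %s\n",
              if (is.na(object@stabilizationSize)) "not reached"
              else format(object@stabilizationSize)))
})
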
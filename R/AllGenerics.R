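#' Sampling rate of a time-resolved object
#'
#' @param x A [FeatureMatrix-class], [EEGRecording-class], [TRF-class] or
#'   [TrialSet-class] object.
#' @return Sampling rate in Hz (a single positive numeric).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Feature names of an object
#'
#' @param x An object carrying named stimulus features.
#' @return Character vector of feature labels, in row/array order.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Channel names of a recording or model
#'
#' @param x An [EEGRecording-class] or [TRF-class] object.
#' @return Character vector of channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Number of channels
#' @param x An object with EEG channels.
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of time samples
#' @param x A time-resolved object.
#' @return Integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Delay grid of a receptive-field object
#'
#' @param x A [TRF-class] or [LaggedDesign-class] object.
#' @return Numeric vector of time delays in seconds, ascending, starting at 0.
#' @export
setGeneric("delayGrid", function(x) standardGeneric("delayGrid"))

#' Regularization strength used by a fitted model
#' @param x A [TRFModel-class] object.
#' @return The ridge penalty (alpha) the model was fitted with.
#' @export
setGeneric("alphaUsed", function(x) standardGeneric("alphaUsed"))

#' Total training duration of a fitted model
#' @param x A [TRFModel-class] object.
#' @return Training duration in seconds.
#' @export
setGeneric("trainingSeconds", function(x) standardGeneric("trainingSeconds"))

#' Trial roles of a trial set
#' @param x A [TrialSet-class] object.
#' @return Named character vector mapping trial id to role
#'   (`train`, `test`, or `test-repeat`).
#' @export
setGeneric("trialRoles", function(x) standardGeneric("trialRoles"))

#' Repeated-presentation groups of a trial set
#' @param x A [TrialSet-class] object.
#' @return Named list mapping each repeated test stimulus id to the trial ids of
#'   its presentations.
#' @export
setGeneric("repeatGroups", function(x) standardGeneric("repeatGroups"))

#' Training-set sizes of a learning curve
#' @param x A [LearningCurve-class] object.
#' @return Integer vector of training-set sizes (trials/chunks), ascending.
#' @export
setGeneric("curveSizes", function(x) standardGeneric("curveSizes"))

#' Training-set sizes of a learning curve, in seconds
#' @param x A [LearningCurve-class] object.
#' @return Numeric vector: size times the mean trial duration.
#' @export
setGeneric("curveSeconds", function(x) standardGeneric("curveSeconds"))

#' Bootstrap replicate scores of a learning curve
#' @param x A [LearningCurve-class] object.
#' @return Numeric matrix, sizes by replicates, of channel-averaged correlations.
#' @export
setGeneric("replicateScores", function(x) standardGeneric("replicateScores"))

#' Mean learning curve over bootstrap replicates
#' @param x A [LearningCurve-class] object.
#' @return Numeric vector of per-size replicate means.
#' @export
setGeneric("curveMean", function(x) standardGeneric("curveMean"))

#' Bootstrap standard error of the learning curve
#' @param x A [LearningCurve-class] object.
#' @return Numeric vector of per-size standard errors across replicates.
#' @export
setGeneric("curveSE", function(x) standardGeneric("curveSE"))

#' Models refitted along the designated replicate of a learning curve
#' @param x A [LearningCurve-class] object built with `keepModels = TRUE`.
#' @return List of [TRFModel-class] objects, one per size.
#' @export
setGeneric("refModels", function(x) standardGeneric("refModels"))

#' Detected knee point of a learning curve
#' @param x A [KneeResult-class] object.
#' @return The training-set size at maximal curvature magnitude (NA if invalid).
#' @export
setGeneric("kneeSize", function(x) standardGeneric("kneeSize"))

#' Detected knee point in seconds of training data
#' @param x A [KneeResult-class] object.
#' @return Knee size times the mean trial duration (NA if unknown or invalid).
#' @export
setGeneric("kneeSeconds", function(x) standardGeneric("kneeSeconds"))

#' Is the knee estimate valid?
#' @param x A [KneeResult-class] object.
#' @return `TRUE` if a usable knee was found, otherwise `FALSE`.
#' @export
setGeneric("kneeValid", function(x) standardGeneric("kneeValid"))

#' Curvature series underlying a knee estimate
#' @param x A [KneeResult-class] object.
#' @return Numeric vector of curvature values along the size grid
#'   (NA where the estimate is undefined).
#' @export
setGeneric("curvatureValues", function(x) standardGeneric("curvatureValues"))

#' Adjacent-weight correlations of a stability curve
#' @param x A [StabilityCurve-class] object.
#' @return Numeric vector of Pearson correlations between flattened weights of
#'   consecutive training-set sizes.
#' @export
setGeneric("adjacentR", function(x) standardGeneric("adjacentR"))

#' First size after which adjacent-weight correlation stays high
#' @param x A [StabilityCurve-class] object.
#' @return The first size from which all subsequent adjacent correlations are at
#'   or above the threshold, or NA if stabilization never occurs.
#' @export
setGeneric("stabilizationSize", function(x) standardGeneric("stabilizationSize"))
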
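#' @include encoding.R
NULL

#' Bootstrap learning curve over increasing training-set sizes
#'
#' Implements the incremental-training protocol: starting from `startSize`
#' trials and growing by `step`, the model is refitted `nBoot` times per size
#' on random subsets of the training pool and scored (channel-averaged Pearson
#' correlation) against a fixed held-out test set. Each bootstrap replicate is
#' a seeded random permutation of the pool and the subset at size x is its
#' first x elements, so training sets grow incrementally within a replicate
#' (one added trial at a time) and are random across replicates; sampling is
#' without replacement within a subset. A with-replacement mode draws an
#' independent subset per size instead. When the test set has repeated
#' presentations, their neural responses are averaged before scoring; the test
#' set is identical for every size and replicate.
#'
#' @param trials A [TrialSet-class] with `train` trials (the pool) and a
#'   nonempty test set (`test` or `test-repeat` roles).
#' @param alpha Ridge penalty shared by every fit (select it once on the full
#'   training set, e.g. with [selectAlpha()]).
#' @param startSize First training-set size (default 10 trials).
#' @param step Size increment (default 1).
#' @param nBoot Bootstrap replicates per size (default 10).
#' @param seed Integer seed; the curve is fully reproducible from it.
#' @param delaySpan Delay window in seconds.
#' @param keepModels Keep the [TRFModel-class] sequence of the first replicate
#'   (needed for [weightStability()]).
#' @param replace Draw subsets with replacement (independent across sizes)
#'   instead of the default nested without-replacement growth.
#' @return A [LearningCurve-class].
#' @seealso [kneePoint()], [weightStability()]
#' @export
learningCurve <- function(trials, alpha, startSize = 10L, step = 1L,
                          nBoot = 10L, seed = 1L, delaySpan = c(0, 0.6),
                          keepModels = TRUE, replace = FALSE) {
  if (startSize < 1L) stop("startSize must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  if (nBoot < 1L) stop("nBoot must be >= 1")
  pool <- trialList(trials, "train")
  testSet <- assembleTestSet(trials)
  if (!length(pool)) stop("training pool is empty")
  if (!length(testSet$trials)) stop("test set is empty")
  checkNoLeakage(pool, testSet$trials)
  if (length(pool) < startSize)
    stop("training pool (", length(pool), ") smaller than startSize (",
         startSize, ")")
  grams <- trialGrams(pool, delaySpan)
  nd <- grams$nd
  Xtest <- do.call(rbind, lapply(testSet$trials, function(tr)
    laggedMatrix(tr$features@values, nd)))
  Ytest <- do.call(cbind, lapply(testSet$trials, function(tr) tr$eeg@values))
  sizes <- seq.int(startSize, length(pool), by = step)
  scores <- matrix(NA_real_, length(sizes), nBoot)
  models <- if (keepModels) vector("list", length(sizes)) else list()
  perms <- lapply(seq_len(nBoot), function(b)
    withSeed(deriveSeed(seed, "bootperm", b), sample.int(length(pool))))
  for (si in seq_along(sizes)) {
    x <- sizes[si]
    for (b in seq_len(nBoot)) {
      idx <- if (replace)
        withSeed(deriveSeed(seed, "bootdraw", si * 1000L + b),
                 sample.int(length(pool), x, replace = TRUE))
      else perms[[b]][seq_len(x)]
      s <- sumGrams(grams, idx)
      W <- solveRidge(s$XtX, s$XtY, alpha)
      pred <- Xtest %*% W
      r <- channelCorrelations(t(pred), Ytest)
      scores[si, b] <- mean(r, na.rm = TRUE)
      if (keepModels && b == 1L)
        models[[si]] <- gramsToModel(grams, idx, alpha)
    }
  }
  secondsPerTrial <- mean(grams$nSamples) / grams$rate
  new("LearningCurve", sizes = as.integer(sizes),
      secondsPerTrial = secondsPerTrial, scores = scores,
      nBoot = as.integer(nBoot), models = models, alpha = alpha)
}

# Fixed test set: repeated presentations averaged per stimulus, plain test
# trials used as-is.
assembleTestSet <- function(trials) {
  if (is(trials, "TrialSet") && length(trials@repeatGroups)) {
    ids <- vapply(trials@trials, function(tr) tr$id, character(1))
    testTrials <- lapply(names(trials@repeatGroups), function(g) {
      members <- match(trials@repeatGroups[[g]], ids)
      eegs <- lapply(trials@trials[members], function(tr) tr$eeg@values)
      avg <- Reduce(`+`, eegs) / length(eegs)
      first <- trials@trials[[members[1L]]]
      list(id = g, features = first$features,
           eeg = EEGRecording(avg, samplingRate(first$eeg),
                              channelNames(first$eeg)),
           role = "test")
    })
    return(list(trials = testTrials, averaged = TRUE))
  }
  list(trials = trialList(trials, c("test", "test-repeat")), averaged = FALSE)
}

checkNoLeakage <- function(pool, testTrials) {
  poolIds <- vapply(pool, function(tr) tr$id, character(1))
  testIds <- vapply(testTrials, function(tr) tr$id, character(1))
  if (length(intersect(poolIds, testIds)))
    stop("test set overlaps the training pool (shared trial ids): ",
         paste(intersect(poolIds, testIds), collapse = ", "))
  for (tt in testTrials)
    for (tr in pool)
      if (identical(dim(tt$features@values), dim(tr$features@values)) &&
          isTRUE(all.equal(tt$features@values, tr$features@values,
                           tolerance = 0)))
        stop("test set overlaps the training pool: trial '", tr$id,
             "' has the same stimulus content as test '", tt$id, "'")
  invisible(TRUE)
}

#' Knee point of a learning curve by curvature maximization
#'
#' The mean curve is mapped to the unit square (both axes normalized to
#' `[0, 1]`, the convention of knee-detection methods on performance curves),
#' smoothed, and differentiated; the knee is the size maximizing the curvature
#' magnitude `|K| = |f''| / (1 + f'^2)^(3/2)`. Derivatives come from a cubic
#' smoothing spline: when the curve is effectively noiseless (tiny
#' second-difference noise) the spline smoothness is chosen by generalized
#' cross-validation, otherwise the curve is presmoothed with a centered moving
#' average of `smoothWindow` points and fitted with a conservative spline
#' (`noisyDf` equivalent degrees of freedom) so bootstrap noise cannot fake a
#' knee. The estimate is declared invalid when the curve does not rise, the
#' curvature is flat (straight line), or the argmax falls within
#' `boundaryMargin` of either end of the size grid — mirroring subjects for
#' whom no knee can be computed.
#'
#' @param curve A [LearningCurve-class], or a numeric vector of curve values
#'   (then supply `sizes`).
#' @param sizes Numeric size grid when `curve` is a plain vector.
#' @param smoothWindow Moving-average width (points) for the noisy branch.
#' @param boundaryMargin Fraction of the grid near each end where a knee is
#'   not trusted (default 0.05).
#' @param noisyDf Spline equivalent degrees of freedom in the noisy branch.
#' @return A [KneeResult-class].
#' @examples
#' x <- 1:60
#' y <- 1 - exp(-x / 12)
#' kneePoint(y, sizes = x)
#' @export
kneePoint <- function(curve, sizes = NULL, smoothWindow = 5L,
                      boundaryMargin = 0.05, noisyDf = 7) {
  if (is(curve, "LearningCurve")) {
    y <- curveMean(curve)
    x <- as.numeric(curveSizes(curve))
    spt <- curve@secondsPerTrial
  } else {
    y <- as.numeric(curve)
    if (is.null(sizes)) stop("sizes are required for a plain numeric curve")
    x <- as.numeric(sizes)
    spt <- NA_real_
  }
  n <- length(y)
  if (n < 7L) stop("need at least 7 curve points for curvature estimation")
  if (n < smoothWindow)
    stop("fewer curve points (", n, ") than the smoothing window (",
         smoothWindow, ")")
  if (diff(range(y)) == 0)
    return(invalidKnee(x, "curve is constant (no rise)", spt))
  xs <- norm01(x)
  ys <- norm01(y)
  sigma <- stats::median(abs(diff(ys, differences = 2L))) / 1.652
  if (sigma <= 0.005) {
    sp <- stats::smooth.spline(xs, ys)
  } else {
    ysm <- movingAverage(ys, smoothWindow)
    keep <- !is.na(ysm)
    sp <- stats::smooth.spline(xs[keep], ysm[keep],
                               df = min(noisyDf, sum(keep) - 2L))
  }
  d1 <- stats::predict(sp, xs, deriv = 1L)$y
  d2 <- stats::predict(sp, xs, deriv = 2L)$y
  K <- d2 / (1 + d1^2)^1.5
  K[c(1L, n)] <- NA_real_
  yhat <- stats::predict(sp, xs)$y
  if (yhat[n] - yhat[1L] <= 0)
    return(invalidKnee(x, "curve does not rise", spt, K))
  i <- which.max(abs(K))
  if (max(abs(K), na.rm = TRUE) < 1e-6)
    return(invalidKnee(x, "curvature is flat (straight-line curve)", spt, K))
  lo <- 1 + boundaryMargin * (n - 1)
  hi <- n - boundaryMargin * (n - 1)
  if (i < lo || i > hi)
    return(invalidKnee(x, sprintf(
      "curvature maximum at the grid boundary (index %d of %d)", i, n),
      spt, K))
  new("KneeResult", kneeSize = x[i],
      kneeSeconds = if (is.na(spt)) NA_real_ else x[i] * spt,
      sizes = x, curvature = K, valid = TRUE, reason = "")
}

invalidKnee <- function(x, reason, spt,
                        K = rep(NA_real_, length(x))) {
  new("KneeResult", kneeSize = NA_real_, kneeSeconds = NA_real_, sizes = x,
      curvature = K, valid = FALSE, reason = reason)
}

#' Grand-average knee point over subjects
#'
#' Mean and standard error over the valid knees only; subjects without a
#' computable knee are counted and reported, never imputed.
#'
#' @param results List of [KneeResult-class] objects (one per subject).
#' @return List with `mean`, `se` (NA when only one valid knee), `nValid`,
#'   `nInvalid`, and `knees` (the valid knee sizes).
#' @export
grandAverageKnee <- function(results) {
  valid <- Filter(kneeValid, results)
  if (!length(valid))
    stop("no knee point could be computed for any subject")
  knees <- vapply(valid, kneeSize, numeric(1))
  list(mean = mean(knees),
       se = if (length(knees) > 1L) stats::sd(knees) / sqrt(length(knees))
            else NA_real_,
       nValid = length(knees),
       nInvalid = length(results) - length(valid),
       knees = knees)
}

#' Adjacent-weight stability across training-set sizes
#'
#' Pearson correlation between the flattened weight arrays of models fitted at
#' consecutive training-set sizes. As data accumulate the receptive field
#' structure stops changing and the correlations approach 1; the
#' stabilization size is the first size after which every subsequent
#' correlation stays at or above the threshold.
#'
#' @param models A [LearningCurve-class] built with `keepModels = TRUE`, or a
#'   list of [TRFModel-class] objects ordered by size.
#' @param sizes Sizes associated with the models (defaults to the curve's
#'   sizes, or `seq_along(models)` for a plain list).
#' @param threshold Stability threshold on the adjacent correlation
#'   (default 0.9).
#' @return A [StabilityCurve-class]; its sizes run from the second model's
#'   size onward.
#' @export
weightStability <- function(models, sizes = NULL, threshold = 0.9) {
  if (is(models, "LearningCurve")) {
    if (is.null(sizes)) sizes <- as.numeric(curveSizes(models))
    models <- refModels(models)
    if (!length(models))
      stop("the learning curve was built with keepModels = FALSE")
  }
  if (length(models) < 2L) stop("need at least 2 models")
  if (is.null(sizes)) sizes <- seq_along(models)
  dims <- lapply(models, function(m) dim(weights(m)))
  if (!all(vapply(dims[-1L], identical, logical(1), dims[[1L]])))
    stop("all models must have identical weight array shapes")
  r <- vapply(seq_len(length(models) - 1L), function(i)
    stats::cor(as.numeric(weights(models[[i]])),
               as.numeric(weights(models[[i + 1L]]))), numeric(1))
  outSizes <- sizes[-1L]
  below <- which(r < threshold)
  stab <- if (!length(below)) outSizes[1L]
          else if (max(below) == length(r)) NA_real_
          else outSizes[max(below) + 1L]
  new("StabilityCurve", sizes = as.numeric(outSizes), adjacentR = r,
      stabilizationSize = as.numeric(stab), threshold = threshold)
}

#' Tidy table of learning-curve replicate scores
#'
#' @param curve A [LearningCurve-class].
#' @param subject Subject label for the table.
#' @param label Model/feature-set label for the table.
#' @return Data frame with columns `subject`, `model`, `size`, `seconds`,
#'   `replicate`, `score`.
#' @export
learningCurveTable <- function(curve, subject = "S01", label = "full") {
  sc <- replicateScores(curve)
  data.frame(
    subject = subject, model = label,
    size = rep(curveSizes(curve), ncol(sc)),
    seconds = rep(curveSeconds(curve), ncol(sc)),
    replicate = rep(seq_len(ncol(sc)), each = nrow(sc)),
    score = as.numeric(sc),
    stringsAsFactors = FALSE)
}

#' Plot a learning curve with its knee
#'
#' Mean curve with a bootstrap standard-error band, and the knee location when
#' a valid [KneeResult-class] is supplied.
#'
#' @param x A [LearningCurve-class].
#' @param y Optional [KneeResult-class] to mark.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
setMethod("plot", signature(x = "LearningCurve"), function(x, y = NULL, ...) {
  m <- curveMean(x)
  se <- curveSE(x)
  s <- curveSizes(x)
  graphics::plot(s, m, type = "l", lwd = 2, col = "steelblue4",
                 xlab = "training-set size (trials)",
                 ylab = "mean test correlation (r)", ...)
  graphics::polygon(c(s, rev(s)), c(m - se, rev(m + se)), border = NA,
                    col = grDevices::adjustcolor("steelblue4", 0.2))
  if (!is.null(y) && is(y, "KneeResult") && kneeValid(y))
    graphics::abline(v = kneeSize(y), lty = 2)
  invisible(x)
})
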
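#' @include utils.R
NULL

#' Default ridge penalty grid
#'
#' Fifteen log-spaced values between 1e2 and 1e8 inclusive, the standard grid
#' for speech-EEG encoding models.
#'
#' @return Numeric vector of length 15.
#' @examples
#' range(defaultAlphaGrid())  # 1e2 1e8
#' @export
defaultAlphaGrid <- function() 10^seq(2, 8, length.out = 15L)

#' Build the time-lagged stimulus design matrix
#'
#' Column (f, tau) at row t holds feature f shifted by tau; entries that would
#' reference time before the trial onset are zero. Delays run from 0 to
#' `delaySpan[2]` on the sampling grid (`floor(d_max * rate) + 1` delays, so
#' 77 columns per feature for 600 ms at 128 Hz).
#'
#' @param features A [FeatureMatrix-class] (or plain matrix plus `rate`).
#' @param delaySpan `c(0, d_max)` in seconds.
#' @param rate Sampling rate in Hz; taken from `features` when it is a
#'   [FeatureMatrix-class].
#' @return A [LaggedDesign-class].
#' @examples
#' fm <- FeatureMatrix(matrix(c(1, 0, 0, 0), 1), 128, "imp")
#' d <- buildLaggedDesign(fm, c(0, 2 / 128))
#' d@matrix  # shifted copies of the impulse
#' @export
buildLaggedDesign <- function(features, delaySpan = c(0, 0.6), rate = NULL) {
  if (is(features, "FeatureMatrix")) {
    rate <- samplingRate(features)
    fn <- featureNames(features)
    vals <- features@values
  } else {
    if (is.null(rate)) stop("rate is required for a plain matrix")
    vals <- as.matrix(features)
    fn <- rownames(vals)
    if (is.null(fn)) fn <- sprintf("f%d", seq_len(nrow(vals)))
  }
  if (length(delaySpan) != 2L || delaySpan[1L] != 0 || delaySpan[2L] <= 0)
    stop("delaySpan must be c(0, d_max) with d_max > 0")
  nd <- nDelays(delaySpan[2L], rate)
  delays <- (seq_len(nd) - 1L) / rate
  X <- laggedMatrix(vals, nd)
  colnames(X) <- paste(rep(fn, each = nd), rep(seq_len(nd) - 1L, length(fn)),
                       sep = "_lag")
  new("LaggedDesign", matrix = X, delayGrid = delays, featureNames = fn,
      samplingRate = as.numeric(rate))
}

# Plain lagged matrix: T x (F*nd), delay-fastest within feature, zero history.
laggedMatrix <- function(vals, nd) {
  nF <- nrow(vals)
  nT <- ncol(vals)
  X <- matrix(0, nT, nF * nd)
  for (f in seq_len(nF)) {
    sf <- vals[f, ]
    base <- (f - 1L) * nd
    for (d in seq_len(nd) - 1L) {
      if (d >= nT) break
      X[(d + 1L):nT, base + d + 1L] <- sf[seq_len(nT - d)]
    }
  }
  X
}

# Solve (XtX + alpha I) W = XtY; Cholesky with an eigendecomposition fallback
# for near-singular Gram matrices.
solveRidge <- function(XtX, XtY, alpha) {
  p <- nrow(XtX)
  A <- XtX + diag(alpha, p)
  W <- tryCatch(chol2inv(chol(A)) %*% XtY, error = function(e) NULL)
  if (is.null(W)) {
    e <- eigen(XtX, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    W <- e$vectors %*% (crossprod(e$vectors, XtY) / (lam + alpha))
  }
  W
}

#' Ridge regression fit of a TRF on one lagged design
#'
#' Per channel n, the weights solve `(X'X + alpha I) w = X'Y[n]` — the
#' standard L2-penalized least squares for the encoding model.
#'
#' @param design A [LaggedDesign-class].
#' @param response An [EEGRecording-class] with as many samples as the design
#'   has rows.
#' @param alpha Positive ridge penalty.
#' @return A [TRFModel-class].
#' @export
ridgeFit <- function(design, response, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  X <- design@matrix
  Y <- t(response@values)
  if (nrow(X) != nrow(Y))
    stop("design rows (", nrow(X), ") must equal response samples (",
         nrow(Y), ")")
  stopIfNotFinite(X, "design")
  stopIfNotFinite(Y, "response")
  W <- solveRidge(crossprod(X), crossprod(X, Y), alpha)
  weightsToModel(W, design, alpha,
                 trainingSeconds = nrow(X) / design@samplingRate,
                 channelNames = channelNames(response))
}

weightsToModel <- function(W, design, alpha, trainingSeconds, channelNames) {
  nd <- length(design@delayGrid)
  nF <- length(design@featureNames)
  arr <- array(0, dim = c(nF, nd, ncol(W)),
               dimnames = list(design@featureNames, NULL, channelNames))
  for (ch in seq_len(ncol(W)))
    arr[, , ch] <- t(matrix(W[, ch], nd, nF))
  new("TRFModel", weights = arr, delayGrid = design@delayGrid,
      featureNames = design@featureNames,
      samplingRate = design@samplingRate, alpha = alpha,
      trainingSeconds = trainingSeconds)
}

# Per-trial Gram contributions for a set of trials: X'X and X'Y per trial,
# so that any training subset's normal equations are sums over its trials.
trialGrams <- function(trials, delaySpan) {
  rate <- samplingRate(trials[[1L]]$features)
  nd <- nDelays(delaySpan[2L], rate)
  fn <- featureNames(trials[[1L]]$features)
  G <- vector("list", length(trials))
  B <- vector("list", length(trials))
  nSamp <- integer(length(trials))
  for (i in seq_along(trials)) {
    X <- laggedMatrix(trials[[i]]$features@values, nd)
    Y <- t(trials[[i]]$eeg@values)
    G[[i]] <- crossprod(X)
    B[[i]] <- crossprod(X, Y)
    nSamp[i] <- nrow(X)
  }
  list(G = G, B = B, nSamples = nSamp, rate = rate, nd = nd,
       featureNames = fn,
       channelNames = channelNames(trials[[1L]]$eeg))
}

sumGrams <- function(grams, idx) {
  XtX <- grams$G[[idx[1L]]]
  XtY <- grams$B[[idx[1L]]]
  for (i in idx[-1L]) {
    XtX <- XtX + grams$G[[i]]
    XtY <- XtY + grams$B[[i]]
  }
  list(XtX = XtX, XtY = XtY, n = sum(grams$nSamples[idx]))
}

gramsToModel <- function(grams, idx, alpha) {
  s <- sumGrams(grams, idx)
  W <- solveRidge(s$XtX, s$XtY, alpha)
  nd <- grams$nd
  fn <- grams$featureNames
  arr <- array(0, dim = c(length(fn), nd, ncol(W)),
               dimnames = list(fn, NULL, grams$channelNames))
  for (ch in seq_len(ncol(W)))
    arr[, , ch] <- t(matrix(W[, ch], nd, length(fn)))
  new("TRFModel", weights = arr,
      delayGrid = (seq_len(nd) - 1L) / grams$rate, featureNames = fn,
      samplingRate = grams$rate, alpha = alpha,
      trainingSeconds = s$n / grams$rate)
}

#' Fit a TRF on the training trials of a TrialSet
#'
#' Builds the lagged design per trial (zero stimulus history at each trial
#' onset, so no cross-trial leakage), stacks the normal equations, and solves
#' the ridge system once per channel.
#'
#' @param trials A [TrialSet-class] or a list of trials (`features` + `eeg`).
#' @param alpha Positive ridge penalty.
#' @param delaySpan Delay window `c(0, d_max)` in seconds.
#' @param role Which trials to use when `trials` is a [TrialSet-class]
#'   (default `"train"`).
#' @return A [TRFModel-class].
#' @export
fitTrf <- function(trials, alpha, delaySpan = c(0, 0.6), role = "train") {
  tl <- trialList(trials, role)
  if (!length(tl)) stop("no trials with role ", sQuote(role))
  grams <- trialGrams(tl, delaySpan)
  gramsToModel(grams, seq_along(tl), alpha)
}

trialList <- function(trials, role = NULL) {
  if (is(trials, "TrialSet")) {
    tl <- trials@trials
    if (!is.null(role)) tl <- Filter(function(tr) tr$role %in% role, tl)
    tl
  } else trials
}

#' Select the ridge penalty by cross-validation on the training set
#'
#' Training trials are partitioned into contiguous folds; for every candidate
#' penalty the model is fitted on all-but-one fold and scored (channel-averaged
#' Pearson correlation) on the held-out fold; scores are averaged over channels
#' first, then over folds. The chosen penalty maximizes that mean, ties broken
#' toward the larger (more regularized) value. The eigendecomposition of each
#' fold's Gram matrix is reused across the whole grid (fit once, shrink many).
#'
#' @param trials A [TrialSet-class] (its `train` trials are used) or a list of
#'   trials.
#' @param config A [RidgeConfig-class]: candidate grid, fold count, delays.
#' @param seed Unused by the deterministic contiguous partition; kept so
#'   callers can thread one seed through every stage.
#' @return List with `alpha` (chosen penalty) and `scores` (data frame of
#'   per-alpha mean validation correlation).
#' @export
selectAlpha <- function(trials, config = RidgeConfig(), seed = 1L) {
  tl <- trialList(trials, "train")
  k <- config@nFolds
  if (length(tl) < k)
    stop("need at least nFolds (", k, ") training trials, got ", length(tl))
  alphas <- config@alphas
  grams <- trialGrams(tl, config@delaySpan)
  total <- sumGrams(grams, seq_along(tl))
  foldId <- cut(seq_along(tl), breaks = k, labels = FALSE)
  foldScores <- matrix(NA_real_, k, length(alphas))
  for (f in seq_len(k)) {
    inFold <- which(foldId == f)
    s <- sumGrams(grams, inFold)
    XtX <- total$XtX - s$XtX
    XtY <- total$XtY - s$XtY
    e <- eigen(XtX, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    proj <- crossprod(e$vectors, XtY)
    Xv <- do.call(rbind, lapply(inFold, function(i)
      laggedMatrix(tl[[i]]$features@values, grams$nd)))
    Yv <- do.call(cbind, lapply(inFold, function(i) tl[[i]]$eeg@values))
    for (a in seq_along(alphas)) {
      W <- e$vectors %*% (proj / (lam + alphas[a]))
      pred <- Xv %*% W
      r <- channelCorrelations(t(pred), Yv)
      foldScores[f, a] <- if (all(is.na(r))) 0 else mean(r, na.rm = TRUE)
    }
  }
  meanScores <- colMeans(foldScores)
  best <- which(meanScores >= max(meanScores) - 1e-12)
  list(alpha = alphas[max(best)],
       scores = data.frame(alpha = alphas, meanCor = meanScores))
}

#' Predict EEG from stimulus features with a fitted TRF
#'
#' The prediction is the lagged design times the model weights — linear in the
#' features by construction.
#'
#' @param model A [TRFModel-class].
#' @param features A [FeatureMatrix-class] with the model's feature names in
#'   the model's order, at the model's sampling rate.
#' @return An [EEGRecording-class] of predicted responses.
#' @export
predictEeg <- function(model, features) {
  if (!identical(featureNames(features), featureNames(model)))
    stop("feature names/order do not match the model")
  if (abs(samplingRate(features) - samplingRate(model)) > 1e-9)
    stop("feature sampling rate (", samplingRate(features),
         ") does not match the model delay grid rate (",
         samplingRate(model), ")")
  nd <- length(delayGrid(model))
  X <- laggedMatrix(features@values, nd)
  W <- weights(model)
  Wmat <- matrix(0, ncol(X), dim(W)[3L])
  for (f in seq_len(dim(W)[1L]))
    Wmat[((f - 1L) * nd + 1L):(f * nd), ] <- W[f, , ]
  pred <- X %*% Wmat
  EEGRecording(t(pred), samplingRate(model), channelNames(model))
}

channelCorrelations <- function(a, b) {
  vapply(seq_len(nrow(a)), function(ch) {
    x <- a[ch, ]; y <- b[ch, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
}

#' Score a predicted recording against the actual one
#'
#' Pearson correlation per channel over time; the summary is the unweighted
#' mean across channels. Channels with zero variance in either signal are
#' flagged NA and excluded from the mean.
#'
#' @param predicted,actual [EEGRecording-class] objects of equal shape.
#' @return List with `perChannel` (named numeric, NA where undefined) and
#'   `mean`.
#' @export
scorePrediction <- function(predicted, actual) {
  if (!all(dim(predicted@values) == dim(actual@values)))
    stop("predicted and actual recordings must have equal shapes")
  if (ncol(actual@values) < 3L)
    stop("need at least 3 samples to correlate")
  r <- channelCorrelations(predicted@values, actual@values)
  names(r) <- channelNames(actual)
  list(perChannel = r,
       mean = if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE))
}
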
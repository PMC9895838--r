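# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they share no code path with the implementation.

# Brute-force lagged-sum convolution: EEG(t, n) = sum_f sum_tau w(f,tau,n) *
# s(f, t - tau), zero stimulus before trial onset.
bruteForceConvolve <- function(trf, stim) {
  W <- weights(trf)
  s <- stim@values
  nF <- dim(W)[1L]; nD <- dim(W)[2L]; nC <- dim(W)[3L]
  nT <- ncol(s)
  out <- matrix(0, nC, nT)
  for (ch in seq_len(nC))
    for (f in seq_len(nF))
      for (d in seq_len(nD) - 1L)
        for (t in seq_len(nT))
          if (t - d >= 1L)
            out[ch, t] <- out[ch, t] + W[f, d + 1L, ch] * s[f, t - d]
  out
}

# Explicit normal-equation ridge solution (X'X + alpha I)^-1 X'Y.
ridgeOracle <- function(X, Y, alpha) {
  p <- ncol(X)
  solve(crossprod(X) + diag(alpha, p), crossprod(X, Y))
}

# Dense finite-difference curvature-magnitude argmax on an analytic curve,
# using the same unit-square convention as the package.
denseKneeOracle <- function(fun, xmin, xmax, nDense = 20001L) {
  xd <- seq(xmin, xmax, length.out = nDense)
  yd <- fun(xd)
  xs <- (xd - min(xd)) / diff(range(xd))
  ys <- (yd - min(yd)) / diff(range(yd))
  h <- xs[2L] - xs[1L]
  n <- length(xs)
  d1 <- c(NA, (ys[3:n] - ys[1:(n - 2L)]) / (2 * h), NA)
  d2 <- c(NA, (ys[3:n] - 2 * ys[2:(n - 1L)] + ys[1:(n - 2L)]) / h^2, NA)
  K <- abs(d2 / (1 + d1^2)^1.5)
  xd[which.max(K)]
}

# Small synthetic trial set for protocol-level tests: envelope-only stimuli,
# low channel count, repeated-test design.
makeSmallTrialSet <- function(nTrials = 20L, nTest = 3L, nRepeats = 2L,
                              channels = 2L, duration = 1, snrDb = Inf,
                              seed = 42L, features = "envelope") {
  fn <- unlist(lapply(features, function(f)
    if (f == "phonological-14") phonologicalFeatureNames() else f))
  trf <- makeGroundTruthTrf(fn, channels, 128, seed = seed)
  stims <- simulateStimulus(nTrials, duration, 128, features, seed = seed + 1L)
  noise <- NoiseSpec(snrDb, "white")
  eeg <- simulateEeg(trf, stims, noise, seed = seed + 2L)
  ts <- assembleTrialSet(
    stims, eeg,
    list(type = "repeated-test", nTestStimuli = nTest, nRepeats = nRepeats),
    seed = seed + 3L, trf = trf, noise = noise)
  list(trials = ts, trf = trf, stims = stims)
}

# Minimal KneeResult stand-ins for aggregation tests.
makeKneeResult <- function(size, valid = TRUE) {
  sizes <- seq(0, max(size, 10, na.rm = TRUE) + 10)
  new("KneeResult",
      kneeSize = if (valid) size else NA_real_,
      kneeSeconds = NA_real_, sizes = sizes,
      curvature = rep(NA_real_, length(sizes)),
      valid = valid, reason = if (valid) "" else "synthetic invalid case")
}

# Minimal TRFModel with prescribed weights for stability tests.
makeWeightModel <- function(W, rate = 128) {
  new("TRFModel", weights = W,
      delayGrid = (seq_len(dim(W)[2L]) - 1L) / rate,
      featureNames = sprintf("f%d", seq_len(dim(W)[1L])),
      samplingRate = rate, alpha = 1, trainingSeconds = 1)
}
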
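#' @include utils.R
NULL

#' Number of delay samples for a delay window
#'
#' Delays run from 0 to `dMax` inclusive on the sampling grid, so the count is
#' `floor(dMax * rate) + 1`.
#'
#' @param dMax Maximum delay in seconds.
#' @param rate Sampling rate in Hz.
#' @return Integer number of delays.
#' @export
nDelays <- function(dMax, rate) {
  n <- floor(dMax * rate) + 1L
  if (n < 2L) stop("delay window too short: no usable delays at this rate")
  as.integer(n)
}

#' Build a ground-truth receptive field for simulation
#'
#' Each feature receives a gamma-shaped temporal kernel (smooth, causal, with a
#' single peak) parameterized by its peak latency, width, amplitude and sign.
#' Channels carry scaled copies of the kernel under a smooth sinusoidal gain
#' profile across channel index, giving channel diversity without modeling
#' electrode geometry.
#'
#' @param featureNames Ordered feature labels.
#' @param channelCount Number of EEG channels.
#' @param samplingRate Sampling rate of the simulated EEG, Hz.
#' @param kernelSpec Data frame with one row per feature and columns `latency`
#'   (s, kernel peak), `width` (s, kernel spread), `amplitude` and `sign`
#'   (+1/-1). Defaults to a seeded random specification via
#'   [defaultKernelSpec()].
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @param dMax Maximum delay in seconds (default 0.6).
#' @return A [GroundTruthTRF-class] whose weights are zero outside
#'   `[0, dMax]` by construction.
#' @examples
#' trf <- makeGroundTruthTrf(c("envelope", "pitch"), 8, 128, seed = 1)
#' dim(weights(trf))  # 2 x 77 x 8
#' @export
makeGroundTruthTrf <- function(featureNames, channelCount, samplingRate,
                               kernelSpec = NULL, seed = 1L, dMax = 0.6) {
  featureNames <- as.character(featureNames)
  nF <- length(featureNames)
  if (nF < 1L) stop("at least one feature is required")
  if (channelCount < 1L) stop("channelCount must be positive")
  if (samplingRate <= 0) stop("samplingRate must be positive")
  if (is.null(kernelSpec))
    kernelSpec <- defaultKernelSpec(featureNames, seed = seed)
  if (nrow(kernelSpec) != nF)
    stop("kernelSpec must have one row per feature")
  nd <- nDelays(dMax, samplingRate)
  delays <- (seq_len(nd) - 1L) / samplingRate
  w <- array(0, dim = c(nF, nd, channelCount),
             dimnames = list(featureNames, NULL,
                             sprintf("chan%02d", seq_len(channelCount))))
  withSeed(seed, {
    phases <- stats::runif(nF, 0, 2 * pi)
    for (f in seq_len(nF)) {
      lat <- kernelSpec$latency[f]
      wid <- kernelSpec$width[f]
      amp <- kernelSpec$amplitude[f] * sign(kernelSpec$sign[f])
      if (lat + 3 * wid > dMax + 1e-9)
        stop(sprintf(
          "kernel for feature '%s' extends beyond %.2f s (latency %.3f + 3*width %.3f)",
          featureNames[f], dMax, lat, wid))
      kern <- gammaKernel(delays, lat, wid)
      if (amp == 0) kern <- kern * 0 else kern <- kern * amp
      gains <- 1 + 0.5 * sin(2 * pi * (seq_len(channelCount) - 1L) /
                               max(1L, channelCount) + phases[f])
      for (ch in seq_len(channelCount)) w[f, , ch] <- kern * gains[ch]
    }
  })
  new("GroundTruthTRF", weights = w, delayGrid = delays,
      featureNames = featureNames, samplingRate = as.numeric(samplingRate))
}

# Gamma-shaped kernel with peak (mode) at `latency` and spread ~ `width`,
# normalized to unit peak. latency = 0 degenerates to a decaying exponential.
gammaKernel <- function(t, latency, width) {
  if (latency <= 0) {
    k <- exp(-t / max(width, 1e-6))
    return(k / max(k))
  }
  shape <- (latency / width)^2 + 1
  scale <- latency / (shape - 1)
  logk <- (shape - 1) * log(pmax(t, 1e-12)) - t / scale
  logk <- logk - max(logk)
  k <- exp(logk)
  k[t <= 0] <- if (shape > 1) 0 else 1
  k / max(k)
}

#' Default kernel specification for a ground-truth receptive field
#'
#' Seeded random auditory-plausible kernels: peak latencies 60-350 ms, widths
#' 30-70 ms, unit-scale amplitudes, mostly positive polarity.
#'
#' @param featureNames Feature labels (one kernel per feature).
#' @param seed Integer seed.
#' @return Data frame with columns `feature`, `latency`, `width`, `amplitude`,
#'   `sign`.
#' @export
defaultKernelSpec <- function(featureNames, seed = 1L) {
  nF <- length(featureNames)
  withSeed(deriveSeed(seed, "kernelspec"), {
    data.frame(
      feature = as.character(featureNames),
      latency = stats::runif(nF, 0.06, 0.35),
      width = stats::runif(nF, 0.03, 0.07),
      amplitude = stats::runif(nF, 0.5, 1.5),
      sign = sample(c(-1, 1), nF, replace = TRUE, prob = c(0.3, 0.7)),
      stringsAsFactors = FALSE)
  })
}

#' The 14 phonological feature labels
#'
#' Place/manner-of-articulation classes used as binary onset features, in
#' fixed row order.
#'
#' @return Character vector of length 14.
#' @export
phonologicalFeatureNames <- function() {
  c("sonorant", "obstruent", "voiced", "back", "front", "low", "high",
    "dorsal", "coronal", "labial", "syllabic", "plosive", "fricative", "nasal")
}

#' Simulate stimulus feature streams
#'
#' Generates per-trial [FeatureMatrix-class] objects emulating continuous
#' speech features: a nonnegative low-pass acoustic envelope, a piecewise
#' voiced/unvoiced pitch track, and/or 14 binary phonological onset rows driven
#' by a random phoneme sequence mapped through the shipped phoneme-to-feature
#' table. Trial durations are uniform on `[0.75, 1.25]` times `meanDuration`.
#'
#' @param nTrials Number of trials (>= 1).
#' @param meanDuration Mean trial duration in seconds.
#' @param samplingRate Sampling rate in Hz.
#' @param featureConfig Character subset of
#'   `c("envelope", "pitch", "phonological-14")`.
#' @param seed Integer seed.
#' @return List of [FeatureMatrix-class] objects (length `nTrials`).
#' @examples
#' stims <- simulateStimulus(3, 2, 128, "envelope", seed = 7)
#' nSamples(stims[[1]])
#' @export
simulateStimulus <- function(nTrials, meanDuration = 2, samplingRate = 128,
                             featureConfig = c("envelope", "pitch",
                                               "phonological-14"),
                             seed = 1L) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  if (meanDuration <= 0) stop("meanDuration must be positive")
  valid <- c("envelope", "pitch", "phonological-14")
  bad <- setdiff(featureConfig, valid)
  if (length(bad))
    stop("unknown feature name(s) ", paste(sQuote(bad), collapse = ", "),
         "; valid names are ", paste(sQuote(valid), collapse = ", "))
  fmap <- phonemeFeatureMap()
  lapply(seq_len(nTrials), function(i) {
    withSeed(deriveSeed(seed, "stimulus", i), {
      dur <- stats::runif(1, 0.75, 1.25) * meanDuration
      nT <- max(8L, round(dur * samplingRate))
      rows <- list()
      if ("envelope" %in% featureConfig)
        rows$envelope <- simEnvelopeRow(nT, samplingRate)
      if ("pitch" %in% featureConfig)
        rows$pitch <- simPitchRow(nT, samplingRate)
      if ("phonological-14" %in% featureConfig) {
        ph <- simPhonemeSequence(nT / samplingRate)
        pm <- phonologicalOnsetMatrix(ph, duration = nT / samplingRate,
                                      targetRate = samplingRate,
                                      mapping = fmap)
        for (nm in featureNames(pm)) rows[[nm]] <- pm@values[nm, ]
      }
      vals <- do.call(rbind, rows)
      rownames(vals) <- names(rows)
      FeatureMatrix(vals, samplingRate)
    })
  })
}

# Nonnegative, slow (< ~10 Hz) envelope-like row: rectified low-passed noise.
simEnvelopeRow <- function(nT, rate) {
  x <- stats::rnorm(nT + 64L)
  flt <- signal::butter(4, min(0.95, 8 / (rate / 2)), type = "low")
  sm <- iirFiltFilt(flt, x)
  env <- abs(sm)
  env <- iirFiltFilt(flt, env)
  env <- pmax(env, 0)
  env <- env[33:(32L + nT)]
  env / max(mean(env), 1e-9)
}

# Piecewise voiced/unvoiced f0 track: 0 in unvoiced spans, slowly varying
# 100-250 Hz values in voiced spans.
simPitchRow <- function(nT, rate) {
  out <- numeric(nT)
  base <- stats::runif(1, 110, 220)
  t <- 1L
  voiced <- stats::runif(1) < 0.7
  while (t <= nT) {
    span <- max(2L, round(stats::runif(1, 0.1, 0.35) * rate))
    hi <- min(nT, t + span - 1L)
    if (voiced) {
      drift <- cumsum(stats::rnorm(hi - t + 1L, 0, 0.5))
      out[t:hi] <- pmax(60, base + drift)
    }
    t <- hi + 1L
    voiced <- !voiced
  }
  out
}

# Random phoneme sequence as an annotation data frame (label, start, end).
simPhonemeSequence <- function(duration) {
  inventory <- rownames(phonemeFeatureMap())
  starts <- c()
  labels <- c()
  t <- stats::runif(1, 0, 0.05)
  while (t < duration - 0.02) {
    labels <- c(labels, sample(inventory, 1L))
    starts <- c(starts, t)
    t <- t + stats::runif(1, 0.05, 0.15)
  }
  if (!length(labels))
    return(data.frame(label = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  data.frame(label = labels, start = starts,
             end = c(starts[-1L], min(duration, t)),
             stringsAsFactors = FALSE)
}

#' Simulate EEG as a lagged linear response to stimulus features
#'
#' Each recording is the causal convolution of the stimulus features with the
#' ground-truth receptive field, plus additive noise scaled so the realized
#' per-channel SNR equals `snrDb` exactly (infinite SNR returns the noiseless
#' convolution bit-for-bit). Stimulus history before trial onset is zero.
#'
#' @param trf A [GroundTruthTRF-class].
#' @param stimuli List of [FeatureMatrix-class] objects whose feature names
#'   match `featureNames(trf)` in order.
#' @param noise A [NoiseSpec-class].
#' @param seed Integer seed (per-trial noise streams are derived from it).
#' @return List of [EEGRecording-class] objects, one per stimulus.
#' @examples
#' trf <- makeGroundTruthTrf("envelope", 4, 128, seed = 1)
#' st <- simulateStimulus(1, 2, 128, "envelope", seed = 2)
#' eeg <- simulateEeg(trf, st, NoiseSpec(Inf), seed = 3)
#' @export
simulateEeg <- function(trf, stimuli, noise = NoiseSpec(), seed = 1L) {
  stopifnot(is(trf, "GroundTruthTRF"), is(noise, "NoiseSpec"))
  fn <- featureNames(trf)
  for (s in stimuli) {
    sf <- featureNames(s)
    if (!identical(sf, fn)) {
      bad <- which(sf != fn[seq_along(sf)])[1L]
      if (is.na(bad)) bad <- min(length(sf), length(fn)) + 1L
      stop(sprintf(
        "stimulus feature names do not match the TRF (first mismatch at position %d: '%s' vs '%s')",
        bad, if (bad <= length(sf)) sf[bad] else "<missing>",
        if (bad <= length(fn)) fn[bad] else "<missing>"))
    }
  }
  W <- weights(trf)
  C <- dim(W)[3L]
  lapply(seq_along(stimuli), function(i) {
    s <- stimuli[[i]]@values
    nT <- ncol(s)
    clean <- matrix(0, C, nT)
    for (f in seq_along(fn)) {
      sf <- s[f, ]
      for (ch in seq_len(C)) {
        k <- W[f, , ch]
        if (all(k == 0)) next
        conv <- stats::convolve(sf, rev(k), type = "open")[seq_len(nT)]
        clean[ch, ] <- clean[ch, ] + conv
      }
    }
    if (is.infinite(noise@snrDb)) {
      vals <- clean
    } else {
      nz <- withSeed(deriveSeed(seed, "noise", i), {
        if (noise@spectrum == "pink")
          t(vapply(seq_len(C), function(ch) pinkNoise(nT), numeric(nT)))
        else matrix(stats::rnorm(C * nT), C, nT)
      })
      for (ch in seq_len(C)) {
        pSig <- mean(clean[ch, ]^2)
        pNz <- mean(nz[ch, ]^2)
        sc <- if (pSig > 0 && pNz > 0)
          sqrt(pSig / (pNz * 10^(noise@snrDb / 10))) else 1
        nz[ch, ] <- nz[ch, ] * sc
      }
      if (length(noise@perChannelScale)) {
        if (length(noise@perChannelScale) != C)
          stop("perChannelScale length must equal channel count")
        nz <- nz * noise@perChannelScale
      }
      vals <- clean + nz
    }
    EEGRecording(vals, samplingRate(trf), channelNames(trf))
  })
}

#' Assemble stimuli and recordings into a TrialSet
#'
#' Two designs are supported. `repeated-test`: a seeded random choice of
#' `nTestStimuli` stimuli becomes the test set; each is re-presented
#' `nRepeats` times with independent noise (roles `test-repeat`, grouped in
#' `repeatGroups`), the remainder are training trials. `continuous-split`:
#' the first `trainFraction` of the trials (in order) are training data and
#' the rest are the test set.
#'
#' @param stimuli List of [FeatureMatrix-class] objects.
#' @param recordings List of [EEGRecording-class] objects (same length).
#' @param design Either `list(type = "repeated-test", nTestStimuli =, nRepeats =)`
#'   or `list(type = "continuous-split", trainFraction =)`.
#' @param seed Integer seed (test-stimulus choice and repeat noise).
#' @param trf,noise Required for `repeated-test`: the [GroundTruthTRF-class]
#'   and [NoiseSpec-class] used to regenerate each repeat with independent
#'   noise.
#' @return A [TrialSet-class].
#' @examples
#' trf <- makeGroundTruthTrf("envelope", 4, 128, seed = 1)
#' st <- simulateStimulus(12, 1, 128, "envelope", seed = 2)
#' eeg <- simulateEeg(trf, st, NoiseSpec(10), seed = 3)
#' ts <- assembleTrialSet(st, eeg,
#'   list(type = "repeated-test", nTestStimuli = 2, nRepeats = 3),
#'   seed = 4, trf = trf, noise = NoiseSpec(10))
#' @export
assembleTrialSet <- function(stimuli, recordings, design, seed = 1L,
                             trf = NULL, noise = NULL) {
  if (length(stimuli) != length(recordings))
    stop("stimuli and recordings must have equal length")
  n <- length(stimuli)
  rate <- samplingRate(stimuli[[1L]])
  ids <- sprintf("trial%03d", seq_len(n))
  type <- design$type
  if (identical(type, "repeated-test")) {
    nTest <- design$nTestStimuli
    nRep <- design$nRepeats
    if (nTest > n) stop("nTestStimuli exceeds the number of available stimuli")
    if (nTest < 1L || nRep < 1L) stop("nTestStimuli and nRepeats must be >= 1")
    testIdx <- withSeed(deriveSeed(seed, "testpick"),
                        sort(sample.int(n, nTest)))
    trials <- list()
    for (i in setdiff(seq_len(n), testIdx))
      trials[[length(trials) + 1L]] <- list(
        id = ids[i], features = stimuli[[i]], eeg = recordings[[i]],
        role = "train")
    groups <- list()
    for (i in testIdx) {
      reps <- if (!is.null(trf)) {
        if (is.null(noise)) noise <- NoiseSpec()
        simulateEeg(trf, rep(stimuli[i], nRep), noise,
                    seed = deriveSeed(seed, "repeat", i))
      } else if (is.infinite(noiseSnr(noise))) {
        rep(recordings[i], nRep)
      } else {
        stop("repeated-test with finite noise needs `trf` (and `noise`) to ",
             "regenerate repeats with independent noise")
      }
      repIds <- sprintf("%s_rep%02d", ids[i], seq_len(nRep))
      for (r in seq_len(nRep))
        trials[[length(trials) + 1L]] <- list(
          id = repIds[r], features = stimuli[[i]], eeg = reps[[r]],
          role = "test-repeat")
      groups[[ids[i]]] <- repIds
    }
    new("TrialSet", trials = trials, samplingRate = rate, repeatGroups = groups)
  } else if (identical(type, "continuous-split")) {
    frac <- design$trainFraction
    if (is.null(frac) || frac <= 0 || frac >= 1)
      stop("trainFraction must be strictly between 0 and 1 ",
           "(the test set must be nonempty)")
    nTrain <- floor(n * frac)
    if (nTrain < 1L) stop("trainFraction leaves no training trials")
    roles <- c(rep("train", nTrain), rep("test", n - nTrain))
    trials <- lapply(seq_len(n), function(i)
      list(id = ids[i], features = stimuli[[i]], eeg = recordings[[i]],
           role = roles[i]))
    new("TrialSet", trials = trials, samplingRate = rate,
        repeatGroups = list())
  } else {
    stop("design$type must be 'repeated-test' or 'continuous-split'")
  }
}

noiseSnr <- function(noise) if (is.null(noise)) Inf else noise@snrDb
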
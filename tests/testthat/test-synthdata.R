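test_that("ground-truth kernels peak at the requested latency and respect amplitude", {
  # dense evaluation of the gamma kernel locates the true peak
  spec <- data.frame(feature = "envelope", latency = 0.1, width = 0.04,
                     amplitude = 1, sign = 1)
  trf <- makeGroundTruthTrf("envelope", 4, 128, kernelSpec = spec, seed = 3)
  k <- weights(trf)[1, , 1]
  expect_equal(which.max(abs(k)) - 1L, round(0.1 * 128))

  zero <- makeGroundTruthTrf(c("a", "b"), 4, 128,
    kernelSpec = data.frame(latency = c(0.1, 0.2), width = 0.04,
                            amplitude = 0, sign = 1), seed = 3)
  expect_true(all(weights(zero) == 0))

  again <- makeGroundTruthTrf("envelope", 4, 128, kernelSpec = spec, seed = 3)
  expect_identical(weights(trf), weights(again))

  expect_error(
    makeGroundTruthTrf("late", 4, 128,
      kernelSpec = data.frame(latency = 0.55, width = 0.1,
                              amplitude = 1, sign = 1), seed = 1),
    "late")
})

test_that("kernels are confined to the 0-0.6 s delay window with smooth channel gains", {
  trf <- makeGroundTruthTrf(c("envelope", "pitch"), 16, 128, seed = 9)
  expect_equal(delayGrid(trf)[1], 0)
  expect_equal(diff(delayGrid(trf))[1], 1 / 128)
  expect_lte(max(delayGrid(trf)), 0.6)
  W <- weights(trf)
  # per-channel copies of one kernel shape: perfect correlation across channels
  r <- cor(W[1, , 1], W[1, , 9])
  expect_gt(abs(r), 0.999)
  expect_true(all(is.finite(W)))
})

test_that("simulated stimuli honor the feature configuration", {
  stims <- simulateStimulus(5, 2, 128, "phonological-14", seed = 2)
  for (s in stims) {
    expect_identical(featureNames(s), phonologicalFeatureNames())
    expect_true(all(s@values %in% c(0, 1)))
  }

  env <- simulateStimulus(3, 2, 128, "envelope", seed = 4)
  for (s in env) {
    expect_true(all(s@values >= 0))
    # low-pass character: nearly all spectral power below 25 Hz
    x <- s@values[1, ] - mean(s@values[1, ])
    p <- Mod(fft(x))^2
    freq <- (seq_along(p) - 1) * 128 / length(p)
    half <- freq <= 64
    expect_gt(sum(p[half & freq < 25]) / sum(p[half]), 0.95)
  }

  pt <- simulateStimulus(3, 2, 128, "pitch", seed = 5)
  for (s in pt) {
    expect_true(all(s@values >= 0))
    expect_true(any(s@values == 0))   # unvoiced spans
  }

  expect_error(simulateStimulus(0, 2, 128, "envelope"), "nTrials")
  expect_error(simulateStimulus(2, 2, 128, "spectrogram"), "spectrogram")
})

test_that("trial durations vary around the requested mean", {
  stims <- simulateStimulus(120, 2, 128, "envelope", seed = 6)
  ns <- vapply(stims, nSamples, integer(1))
  expect_gt(mean(ns), 256 * 0.9)
  expect_lt(mean(ns), 256 * 1.1)
  expect_gt(sd(ns), 0)               # durations actually vary
})

test_that("noiseless simulation equals the brute-force lagged-sum oracle", {
  fn <- c("envelope", "pitch")
  trf <- makeGroundTruthTrf(fn, 4, 128, seed = 21)
  stims <- simulateStimulus(3, 1, 128, c("envelope", "pitch"), seed = 22)
  eeg <- simulateEeg(trf, stims, NoiseSpec(Inf), seed = 23)
  for (i in seq_along(stims)) {
    oracle <- bruteForceConvolve(trf, stims[[i]])
    expect_lt(max(abs(eeg[[i]]@values - oracle)), 1e-10)
  }
  again <- simulateEeg(trf, stims, NoiseSpec(Inf), seed = 23)
  expect_identical(eeg[[1]]@values, again[[1]]@values)
})

test_that("finite-SNR noise is scaled to the target per channel", {
  trf <- makeGroundTruthTrf("envelope", 6, 128, seed = 31)
  stims <- simulateStimulus(2, 2, 128, "envelope", seed = 32)
  clean <- simulateEeg(trf, stims, NoiseSpec(Inf), seed = 33)
  for (spect in c("white", "pink")) {
    noisy <- simulateEeg(trf, stims, NoiseSpec(10, spect), seed = 33)
    for (i in seq_along(stims)) {
      nz <- noisy[[i]]@values - clean[[i]]@values
      snr <- 10 * log10(rowMeans(clean[[i]]@values^2) / rowMeans(nz^2))
      expect_true(all(abs(snr - 10) < 0.5))
    }
  }
})

test_that("zero stimulus with finite SNR yields pure noise", {
  trf <- makeGroundTruthTrf("envelope", 3, 128, seed = 41)
  zeroStim <- list(FeatureMatrix(matrix(0, 1, 256,
    dimnames = list("envelope", NULL)), 128))
  out <- simulateEeg(trf, zeroStim, NoiseSpec(5, "white"), seed = 42)
  expect_gt(sd(out[[1]]@values), 0)
  pred <- predictEeg(trf, zeroStim[[1]])
  expect_true(all(pred@values == 0))
})

test_that("feature-name mismatches between stimulus and TRF are rejected", {
  trf <- makeGroundTruthTrf(c("envelope", "pitch"), 3, 128, seed = 51)
  stim <- simulateStimulus(1, 1, 128, "envelope", seed = 52)
  expect_error(simulateEeg(trf, stim, NoiseSpec(Inf)), "mismatch")
})

test_that("repeated-test design builds the 10 x 10 repeat structure", {
  trf <- makeGroundTruthTrf("envelope", 2, 128, seed = 61)
  stims <- simulateStimulus(20, 0.5, 128, "envelope", seed = 62)
  noise <- NoiseSpec(10, "white")
  eeg <- simulateEeg(trf, stims, noise, seed = 63)
  ts <- assembleTrialSet(stims, eeg,
    list(type = "repeated-test", nTestStimuli = 10, nRepeats = 10),
    seed = 64, trf = trf, noise = noise)
  rg <- repeatGroups(ts)
  expect_length(rg, 10)
  expect_true(all(lengths(rg) == 10))
  roles <- trialRoles(ts)
  expect_equal(sum(roles == "train"), 10)
  expect_equal(sum(roles == "test-repeat"), 100)
  # repeats share stimulus content but carry independent noise
  ids <- rg[[1]]
  expect_identical(ts[[ids[1]]]$features@values, ts[[ids[2]]]$features@values)
  expect_false(identical(ts[[ids[1]]]$eeg@values, ts[[ids[2]]]$eeg@values))
})

test_that("continuous split assigns ordered train/test fractions", {
  trf <- makeGroundTruthTrf("envelope", 2, 64, seed = 71)
  stims <- simulateStimulus(100, 0.25, 64, "envelope", seed = 72)
  eeg <- simulateEeg(trf, stims, NoiseSpec(Inf), seed = 73)
  ts <- assembleTrialSet(stims, eeg,
    list(type = "continuous-split", trainFraction = 0.8), seed = 74)
  roles <- trialRoles(ts)
  expect_equal(unname(table(roles)["train"]), 80, ignore_attr = TRUE)
  expect_equal(unname(table(roles)["test"]), 20, ignore_attr = TRUE)
  expect_true(all(roles[1:80] == "train"))

  expect_error(assembleTrialSet(stims, eeg,
    list(type = "continuous-split", trainFraction = 1.0)), "test set")
  expect_error(assembleTrialSet(stims, eeg,
    list(type = "repeated-test", nTestStimuli = 101, nRepeats = 2),
    trf = trf), "exceeds")
})

test_that("dataset containers round-trip and regenerate byte-identically", {
  build <- function(dir) {
    made <- makeSmallTrialSet(nTrials = 6, nTest = 2, nRepeats = 2,
                              channels = 2, duration = 0.5, snrDb = 10,
                              seed = 81)
    writeDataset(made$trials, dir, meta = list(seed = 81))
    made$trials
  }
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  ts <- build(d1)
  build(d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))

  back <- readDataset(d1)
  expect_equal(trialRoles(back), trialRoles(ts))
  expect_equal(repeatGroups(back), repeatGroups(ts))
  expect_equal(back[[1]]$eeg@values, ts[[1]]$eeg@values, tolerance = 1e-12)
  expect_equal(back[[1]]$features@values, ts[[1]]$features@values,
               tolerance = 1e-12)
})
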
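test_that("envelope of a pure tone recovers its amplitude", {
  fs <- 8000
  t <- (0:(2 * fs - 1)) / fs
  tone <- 0.7 * sin(2 * pi * 440 * t)
  env <- extractEnvelope(tone, fs, 128)
  interior <- env@values[1, 30:(nSamples(env) - 30)]
  expect_lt(max(abs(interior - 0.7)) / 0.7, 0.02)
  expect_identical(featureNames(env), "envelope")
})

test_that("envelope tracks a known 2 Hz amplitude modulator", {
  fs <- 8000
  t <- (0:(4 * fs - 1)) / fs
  modulator <- 1 + 0.8 * sin(2 * pi * 2 * t)
  x <- modulator * sin(2 * pi * 500 * t)
  env <- extractEnvelope(x, fs, 128)
  modRef <- 1 + 0.8 * sin(2 * pi * 2 * (0:(nSamples(env) - 1)) / 128)
  keep <- 30:(nSamples(env) - 30)
  expect_gt(cor(env@values[1, keep], modRef[keep]), 0.99)
})

test_that("envelope is zero for silence and invariant to polarity", {
  fs <- 4000
  silence <- extractEnvelope(numeric(fs), fs, 128)
  expect_true(all(silence@values == 0))
  x <- rnorm(fs)
  e1 <- extractEnvelope(x, fs, 128)
  e2 <- extractEnvelope(-x, fs, 128)
  expect_equal(e1@values, e2@values, tolerance = 1e-12)
  expect_error(extractEnvelope(matrix(rnorm(2000), 2), fs), "downmix")
})

test_that("phonological onsets land on the nearest sample in the mapped rows", {
  ann <- data.frame(label = "B", start = 0.5, end = 0.55)
  pm <- phonologicalOnsetMatrix(ann, duration = 1, targetRate = 128)
  expect_equal(nrow(pm@values), 14)
  active <- c("voiced", "labial", "plosive", "obstruent")
  for (f in active)
    expect_equal(which(pm@values[f, ] == 1), 0.5 * 128 + 1L)
  expect_equal(sum(pm@values), length(active))

  empty <- phonologicalOnsetMatrix(
    data.frame(label = character(), start = numeric(), end = numeric()),
    duration = 1, targetRate = 128)
  expect_true(all(empty@values == 0))
  expect_equal(dim(empty@values), c(14L, 128L))
})

test_that("phonological row sums equal the feature counts of the annotation", {
  fmap <- phonemeFeatureMap()
  set.seed(7)
  labs <- sample(rownames(fmap), 30, replace = TRUE)
  starts <- sort(runif(30, 0, 4.8))
  ann <- data.frame(label = labs, start = starts,
                    end = starts + 0.05)
  pm <- phonologicalOnsetMatrix(ann, duration = 5, targetRate = 128)
  counts <- colSums(fmap[labs, , drop = FALSE])
  expect_equal(rowSums(pm@values), counts[phonologicalFeatureNames()],
               ignore_attr = TRUE)
})

test_that("unknown phonemes error by default, silence markers are skipped", {
  ann <- data.frame(label = c("sil", "QX", "B"),
                    start = c(0, 0.1, 0.2), end = c(0.1, 0.2, 0.3))
  expect_error(phonologicalOnsetMatrix(ann, 1, 128), "QX")
  pm <- phonologicalOnsetMatrix(ann, 1, 128, onUnknown = "skip")
  expect_equal(sum(pm@values), 4)  # only /b/ contributes
  # stress digits are stripped: AA1 -> AA
  pm2 <- phonologicalOnsetMatrix(
    data.frame(label = "AA1", start = 0.25, end = 0.3), 1, 128)
  expect_equal(sum(pm2@values["low", ]), 1)
})

test_that("pitch feature holds values between track points and keeps unvoiced zeros", {
  const <- data.frame(time = c(0, 0.5), f0 = c(200, 200))
  pf <- pitchFeature(const, 1, 128)
  expect_true(all(pf@values[1, 65:128] == 200))

  unvoiced <- data.frame(time = seq(0, 0.9, 0.1), f0 = 0)
  expect_true(all(pitchFeature(unvoiced, 1, 128)@values == 0))

  # alternating 100/200 steps: boundaries within one sample of the oracle
  times <- seq(0, 0.95, by = 0.05)
  f0 <- rep(c(100, 200), length.out = length(times))
  pf2 <- pitchFeature(data.frame(time = times, f0 = f0), 1, 200)
  oracle <- numeric(200)
  grid <- (0:199) / 200
  idx <- findInterval(grid + 1e-12, times)
  oracle[idx > 0] <- f0[idx[idx > 0]]
  expect_lte(sum(pf2@values[1, ] != oracle), length(times))
  expect_error(pitchFeature(data.frame(time = 0, f0 = -1), 1, 128),
               "negative")
})

test_that("matched filter recovers planted stimulus positions at 10 dB SNR", {
  set.seed(11)
  fs <- 2000
  stim <- rnorm(400)
  stimPow <- mean(stim^2)
  hits <- 0L
  for (k in 1:20) {
    pos <- sample(0:2000, 1)
    noise <- rnorm(2600) * sqrt(stimPow / 10)   # 10 dB SNR
    rec <- noise
    rec[(pos + 1):(pos + 400)] <- rec[(pos + 1):(pos + 400)] + stim
    res <- alignMatchFilter(rec, fs, stim, fs, threshold = 0.3)
    if (res$found && abs(res$onset - pos) <= 1) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("matched filter reports identity alignment and absent stimuli", {
  set.seed(12)
  stim <- rnorm(300)
  res <- alignMatchFilter(stim, 1000, stim, 1000)
  expect_true(res$found)
  expect_equal(res$onset, 0L)
  expect_equal(res$offset, 299L)
  expect_equal(res$peakScore, 1, tolerance = 1e-9)

  miss <- alignMatchFilter(rnorm(3000), 1000, stim, 1000, threshold = 0.5)
  expect_false(miss$found)
  expect_true(is.na(miss$onset))
  expect_lt(miss$peakScore, 0.5)
})

test_that("TextGrid and TSV annotations parse into interval tables", {
  tg <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", "xmax = 1", "tiers? <exists>", "size = 1", "item []:",
    "    item [1]:", '        class = "IntervalTier"',
    '        name = "phones"', "        xmin = 0", "        xmax = 1",
    "        intervals: size = 3",
    "        intervals [1]:", "            xmin = 0",
    "            xmax = 0.4", '            text = "sil"',
    "        intervals [2]:", "            xmin = 0.4",
    "            xmax = 0.6", '            text = "B"',
    "        intervals [3]:", "            xmin = 0.6",
    "            xmax = 1", '            text = "AA1"')
  tf <- tempfile(fileext = ".TextGrid")
  writeLines(tg, tf)
  ann <- readTextGrid(tf, "phones")
  expect_equal(ann$label, c("sil", "B", "AA1"))
  expect_equal(ann$start, c(0, 0.4, 0.6))
  expect_equal(ann$end, c(0.4, 0.6, 1))
  expect_error(readTextGrid(tf, "words"), "words")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("label\tstart\tend", "B\t0.1\t0.2", "AA\t0.2\t0.5"), tsv)
  tab <- readPhonemeLabels(tsv)
  expect_equal(tab$label, c("B", "AA"))
  expect_equal(tab$end, c(0.2, 0.5))

  pt <- tempfile(fileext = ".txt")
  writeLines(c("0.00 0", "0.01 120.5", "0.02 118"), pt)
  track <- readPitchTrack(pt)
  expect_equal(track$f0, c(0, 120.5, 118))
})

test_that("WAV files round-trip through the reader and writer", {
  fs <- 8000
  x <- sin(2 * pi * 220 * (0:999) / fs) * 0.5
  for (bits in c(16, 32)) {
    wf <- tempfile(fileext = ".wav")
    writeWave(x, fs, wf, bits = bits)
    back <- readWave(wf)
    expect_equal(back$rate, fs)
    expect_equal(back$channels, 1L)
    tol <- if (bits == 16) 1e-4 else 1e-7
    expect_equal(back$samples, x, tolerance = tol)
  }
  # stereo round-trip keeps channel structure
  st <- rbind(x, -x)
  wf <- tempfile(fileext = ".wav")
  writeWave(st, fs, wf)
  back <- readWave(wf)
  expect_equal(back$channels, 2L)
  expect_equal(dim(back$samples), dim(st))
})
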
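test_that("lagged designs shift an impulse across delay columns", {
  fm <- FeatureMatrix(matrix(c(1, 0, 0, 0), 1), 128, "imp")
  d <- buildLaggedDesign(fm, c(0, 1 / 128))
  expect_equal(unname(d@matrix),
               rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0)))

  fm6 <- FeatureMatrix(matrix(rnorm(2 * 100), 2), 128,
                       c("envelope", "pitch"))
  d6 <- buildLaggedDesign(fm6, c(0, 0.6))
  expect_length(delayGrid(d6), 77)           # floor(0.6 * 128) + 1
  expect_equal(ncol(d6@matrix), 2 * 77)
  # column (f=2, tau=3 samples) equals the shifted second feature
  col <- 77 + 4
  expect_equal(d6@matrix[5:100, col], fm6@values[2, 2:97])
  expect_true(all(d6@matrix[1:3, col] == 0))  # zero pre-onset history

  zero <- buildLaggedDesign(FeatureMatrix(matrix(0, 1, 10), 128, "z"),
                            c(0, 0.05))
  expect_true(all(zero@matrix == 0))
  expect_error(buildLaggedDesign(fm6, c(0, 0.001)), "delay")
})

test_that("ridge solutions match the explicit normal-equation oracle", {
  set.seed(101)
  for (k in 1:10) {
    X <- matrix(rnorm(200 * 30), 200, 30)
    Y <- matrix(rnorm(200 * 3), 200, 3)
    alpha <- 10^runif(1, -2, 4)
    d <- new("LaggedDesign", matrix = X,
             delayGrid = (0:9) / 100,
             featureNames = sprintf("f%d", 1:3), samplingRate = 100)
    fit <- ridgeFit(d, EEGRecording(t(Y), 100), alpha)
    W <- weights(fit)
    flat <- rbind(W[1, , ], W[2, , ], W[3, , ])
    oracle <- ridgeOracle(X, Y, alpha)
    expect_lt(max(abs(flat - oracle)), 1e-8)
  }
})

test_that("ridge limits behave: interpolation at tiny alpha, shrinkage at large", {
  set.seed(102)
  n <- 12
  X <- diag(n)
  Y <- matrix(rnorm(n), n, 1)
  d <- new("LaggedDesign", matrix = X, delayGrid = (0:(n / 2 - 1)) / 100,
           featureNames = c("a", "b"), samplingRate = 100)
  rec <- EEGRecording(t(Y), 100)
  w <- as.numeric(weights(ridgeFit(d, rec, 1e-10)))
  expect_equal(sort(w), sort(as.numeric(Y)), tolerance = 1e-6)

  maxes <- vapply(10^seq(-2, 6, by = 1), function(a)
    max(abs(weights(ridgeFit(d, rec, a)))), numeric(1))
  expect_true(all(diff(maxes) <= 1e-12))

  Xbad <- X; Xbad[1, 1] <- NA
  dbad <- new("LaggedDesign", matrix = Xbad, delayGrid = d@delayGrid,
              featureNames = d@featureNames, samplingRate = 100)
  expect_error(ridgeFit(dbad, rec, 1), "non-finite")
})

test_that("the default alpha grid is 15 log-spaced values from 1e2 to 1e8", {
  g <- defaultAlphaGrid()
  expect_length(g, 15)
  expect_equal(g[1], 1e2)
  expect_equal(g[15], 1e8)
  expect_equal(diff(log10(g)), rep(6 / 14, 14), tolerance = 1e-12)
})

test_that("cross-validated alpha selection favors weak penalties on clean data", {
  made <- makeSmallTrialSet(nTrials = 22, nTest = 2, nRepeats = 2,
                            channels = 2, duration = 1, snrDb = Inf,
                            seed = 201)
  cfg <- RidgeConfig(alphas = 10^seq(-4, 8, length.out = 13), nFolds = 4)
  sel <- selectAlpha(made$trials, cfg, seed = 1)
  # noiseless data: the winner matches the exhaustive per-alpha scan (up to
  # the documented toward-larger tie-break) and sits near the grid minimum
  best <- max(sel$scores$meanCor)
  expect_equal(sel$scores$meanCor[sel$scores$alpha == sel$alpha], best,
               tolerance = 1e-10)
  expect_lte(which(cfg@alphas == sel$alpha), 3L)
  expect_equal(nrow(sel$scores), 13)
})

test_that("degenerate constant responses break alpha ties toward stronger penalty", {
  made <- makeSmallTrialSet(nTrials = 10, nTest = 2, nRepeats = 2,
                            channels = 2, duration = 0.5, snrDb = Inf,
                            seed = 202)
  flat <- made$trials
  flat@trials <- lapply(flat@trials, function(tr) {
    tr$eeg <- EEGRecording(matrix(1, nrow(tr$eeg@values),
                                  ncol(tr$eeg@values)),
                           samplingRate(tr$eeg), channelNames(tr$eeg))
    tr
  })
  sel <- selectAlpha(flat, RidgeConfig(nFolds = 2), seed = 1)
  expect_equal(sel$alpha, 1e8)
})

test_that("predictions are linear and reproduce noiseless training data", {
  made <- makeSmallTrialSet(nTrials = 4, nTest = 2, nRepeats = 2,
                            channels = 3, duration = 1, snrDb = Inf,
                            seed = 301)
  tr <- made$trials[[1]]
  pred <- predictEeg(made$trf, tr$features)
  expect_lt(max(abs(pred@values - tr$eeg@values)), 1e-10)

  zero <- FeatureMatrix(matrix(0, 1, 100, dimnames = list("envelope", NULL)),
                        128)
  expect_true(all(predictEeg(made$trf, zero)@values == 0))

  scaled <- FeatureMatrix(3 * tr$features@values, 128)
  expect_equal(predictEeg(made$trf, scaled)@values, 3 * pred@values,
               tolerance = 1e-12)

  wrongRate <- FeatureMatrix(tr$features@values, 100)
  expect_error(predictEeg(made$trf, wrongRate), "rate")
})

test_that("scores are per-channel Pearson correlations averaged without degenerate channels", {
  set.seed(103)
  a <- EEGRecording(matrix(rnorm(5 * 50), 5), 128)
  b <- EEGRecording(matrix(rnorm(5 * 50), 5), 128)
  sc <- scorePrediction(a, b)
  oracle <- vapply(1:5, function(ch) {
    x <- a@values[ch, ]; y <- b@values[ch, ]
    mean((x - mean(x)) * (y - mean(y))) /
      (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  }, numeric(1))
  expect_equal(unname(sc$perChannel), oracle, tolerance = 1e-12)

  expect_equal(scorePrediction(a, a)$perChannel,
               setNames(rep(1, 5), channelNames(a)), tolerance = 1e-12)
  neg <- EEGRecording(-a@values, 128, channelNames(a))
  expect_equal(unname(scorePrediction(neg, a)$perChannel), rep(-1, 5),
               tolerance = 1e-12)

  # zero-variance channel flagged NA and excluded from the mean
  flat <- a
  flat@values[2, ] <- 7
  scf <- scorePrediction(flat, b)
  expect_true(is.na(scf$perChannel[2]))
  expect_equal(scf$mean, mean(scf$perChannel[-2]))

  # consistent channel permutation leaves the mean unchanged
  perm <- c(3, 1, 5, 2, 4)
  ap <- EEGRecording(a@values[perm, ], 128)
  bp <- EEGRecording(b@values[perm, ], 128)
  expect_equal(scorePrediction(ap, bp)$mean, sc$mean, tolerance = 1e-12)

  expect_error(scorePrediction(EEGRecording(matrix(1:2, 1), 128),
                               EEGRecording(matrix(3:4, 1), 128)),
               "3 samples")
})
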
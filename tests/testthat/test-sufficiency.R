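test_that("knee detection matches the dense curvature oracle on analytic curves", {
  curves <- list(
    quadratic = list(fun = function(z) z^2,
                     x = seq(-1, 1, length.out = 41)),
    saturating = list(fun = function(z) 1 - exp(-z / 15), x = 1:100),
    logistic = list(fun = function(z) 1 / (1 + exp(-(z - 25) / 12)),
                    x = 1:100))
  for (nm in names(curves)) {
    cc <- curves[[nm]]
    oracle <- denseKneeOracle(cc$fun, min(cc$x), max(cc$x))
    res <- kneePoint(cc$fun(cc$x), sizes = cc$x)
    expect_true(kneeValid(res), info = nm)
    step <- diff(cc$x[1:2])
    expect_lte(abs(kneeSize(res) - oracle), step + 1e-9, label = nm)
  }
})

test_that("straight lines and falling curves yield no knee", {
  x <- 1:50
  lin <- kneePoint(0.1 + 0.002 * x, sizes = x)
  expect_false(kneeValid(lin))
  expect_match(lin@reason, "flat|rise")

  falling <- kneePoint(exp(-x / 10), sizes = x)
  expect_false(kneeValid(falling))

  flat <- kneePoint(rep(0.5, 50), sizes = x)
  expect_false(kneeValid(flat))
  expect_error(kneePoint(c(1, 2, 3), sizes = 1:3), "7 curve points")
})

test_that("knees of noisy saturating curves preserve the plateau ordering", {
  x <- 1:100
  ok <- 0L
  for (s in 1:5) {
    set.seed(400 + s)
    kn <- vapply(c(5, 15, 40), function(tau) {
      y <- 1 - exp(-x / tau) + rnorm(100, 0, 0.02)
      r <- kneePoint(y, sizes = x)
      if (kneeValid(r)) kneeSize(r) else NA_real_
    }, numeric(1))
    if (!anyNA(kn) && all(diff(kn) > 0)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("grand-average knees pool valid subjects and count the rest", {
  res <- lapply(c(90, 100, 98), makeKneeResult)
  g <- grandAverageKnee(res)
  expect_equal(g$mean, 96)
  expect_equal(g$nValid, 3)
  expect_equal(g$nInvalid, 0)
  expect_equal(g$se, sd(c(90, 100, 98)) / sqrt(3))

  withInvalid <- c(res, list(makeKneeResult(NA, valid = FALSE)))
  g2 <- grandAverageKnee(withInvalid)
  expect_equal(g2$mean, 96)
  expect_equal(g2$nInvalid, 1)

  single <- grandAverageKnee(list(makeKneeResult(42)))
  expect_equal(single$mean, 42)
  expect_true(is.na(single$se))

  expect_error(grandAverageKnee(list(makeKneeResult(NA, valid = FALSE))),
               "no knee")
})

test_that("weight stability is 1 for identical models and ~0 for independent noise", {
  set.seed(77)
  W <- array(rnorm(4 * 25 * 10), c(4, 25, 10))
  same <- list(makeWeightModel(W), makeWeightModel(W), makeWeightModel(W))
  st <- weightStability(same, sizes = c(10, 11, 12))
  expect_equal(adjacentR(st), c(1, 1), tolerance = 1e-12)
  expect_equal(stabilizationSize(st), 11)

  indep <- lapply(1:3, function(i)
    makeWeightModel(array(rnorm(10000), c(4, 25, 100))))
  st2 <- weightStability(indep, threshold = 0.9)
  expect_true(all(abs(adjacentR(st2)) < 0.05))
  expect_true(is.na(stabilizationSize(st2)))

  bad <- list(makeWeightModel(W),
              makeWeightModel(array(rnorm(4 * 10 * 10), c(4, 10, 10))))
  expect_error(weightStability(bad), "shapes")
})

test_that("stabilization size is the first size after the last dip", {
  W0 <- array(rnorm(2 * 5 * 4), c(2, 5, 4))
  jitter <- function(sd) makeWeightModel(W0 + array(rnorm(40, 0, sd),
                                                    dim(W0)))
  models <- list(jitter(2), jitter(2), jitter(1e-4), jitter(1e-4),
                 jitter(1e-4))
  st <- weightStability(models, sizes = 10:14, threshold = 0.9)
  expect_true(all(adjacentR(st)[3:4] > 0.9))
  # adjacentR[i] is labeled by the later size of the pair; stabilization is
  # the label of the first good pair after the last dip
  expect_equal(stabilizationSize(st),
               (10:14)[-1][max(which(adjacentR(st) < 0.9)) + 1])
})

test_that("the learning curve follows the incremental bootstrap protocol", {
  made <- makeSmallTrialSet(nTrials = 18, nTest = 3, nRepeats = 2,
                            channels = 2, duration = 1, snrDb = Inf,
                            seed = 500)
  lc <- learningCurve(made$trials, alpha = 1e-3, startSize = 10, step = 1,
                      nBoot = 10, seed = 9)
  expect_equal(curveSizes(lc), 10:15)
  expect_equal(dim(replicateScores(lc)), c(6L, 10L))
  expect_true(all(is.finite(replicateScores(lc))))

  # reproducible bit-for-bit from the seed
  lc2 <- learningCurve(made$trials, alpha = 1e-3, startSize = 10, step = 1,
                       nBoot = 10, seed = 9)
  expect_identical(replicateScores(lc), replicateScores(lc2))

  # noiseless: the information in the training set only grows
  m <- curveMean(lc)
  expect_gte(m[length(m)], m[1])

  # models of the designated replicate are kept, one per size
  expect_length(refModels(lc), 6)
  expect_equal(trainingSeconds(refModels(lc)[[1]]) <
               trainingSeconds(refModels(lc)[[6]]), TRUE)
})

test_that("reordering the test set changes no reported number", {
  made <- makeSmallTrialSet(nTrials = 14, nTest = 3, nRepeats = 2,
                            channels = 2, duration = 0.5, snrDb = 10,
                            seed = 501)
  lc1 <- learningCurve(made$trials, alpha = 1, seed = 3, keepModels = FALSE)
  shuffled <- made$trials
  n <- length(shuffled@trials)
  roles <- trialRoles(shuffled)
  testIdx <- which(roles != "train")
  perm <- rev(testIdx)
  shuffled@trials[testIdx] <- shuffled@trials[perm]
  shuffled@repeatGroups <- rev(shuffled@repeatGroups)
  lc2 <- learningCurve(shuffled, alpha = 1, seed = 3, keepModels = FALSE)
  expect_equal(replicateScores(lc1), replicateScores(lc2), tolerance = 1e-12)
})

test_that("training pools that contain the test stimulus are rejected", {
  made <- makeSmallTrialSet(nTrials = 14, nTest = 2, nRepeats = 2,
                            channels = 2, duration = 0.5, snrDb = Inf,
                            seed = 502)
  leaky <- made$trials
  # plant a training trial whose stimulus equals a test stimulus
  testId <- repeatGroups(leaky)[[1]][1]
  tt <- leaky[[testId]]
  leaky@trials[[length(leaky@trials) + 1]] <- list(
    id = "leak", features = tt$features, eeg = tt$eeg, role = "train")
  expect_error(learningCurve(leaky, alpha = 1, startSize = 5, seed = 1),
               "overlap")
})

test_that("learning curves convert sizes to seconds via the mean trial duration", {
  made <- makeSmallTrialSet(nTrials = 15, nTest = 2, nRepeats = 2,
                            channels = 2, duration = 1, snrDb = Inf,
                            seed = 503)
  lc <- learningCurve(made$trials, alpha = 1e-3, startSize = 10,
                      keepModels = FALSE, seed = 1)
  pool <- Filter(function(tr) tr$role == "train", made$trials@trials)
  meanDur <- mean(vapply(pool, function(tr) nSamples(tr$eeg), integer(1))) / 128
  expect_equal(curveSeconds(lc), curveSizes(lc) * meanDur)

  tab <- learningCurveTable(lc, subject = "S01", label = "envelope")
  expect_equal(nrow(tab), length(curveSizes(lc)) * 10)
  expect_named(tab, c("subject", "model", "size", "seconds", "replicate",
                      "score"))
})
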
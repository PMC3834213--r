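test_that("output weights equal the independent pseudoinverse solution", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1); d <- sample(2:6, 1); L <- sample(2:25, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- sample(c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2))))
    m <- elmTrain(X, y, elmConfig(nHidden = L, seed = seed))
    H <- hiddenOracle(m, X)
    betaOracle <- svdPinvOracle(H, y)
    expect_lt(max(abs(m@outputWeights - betaOracle)) /
                max(1, sqrt(sum(betaOracle^2))), 1e-8)
    # MASS::ginv truncates more aggressively; it must never beat the
    # minimum norm at (numerically) equal residual
    if (requireNamespace("MASS", quietly = TRUE)) {
      alt <- drop(MASS::ginv(H) %*% y)
      if (abs(sqrt(sum((H %*% alt - y)^2)) -
              sqrt(sum((H %*% m@outputWeights - y)^2))) < 1e-8) {
        nAlt <- sqrt(sum(alt^2))
        expect_lte(sqrt(sum(m@outputWeights^2)),
                   nAlt + 1e-8 * max(1, nAlt))
      }
    }
  }
})

test_that("the solution is the minimum-norm least-squares minimizer", {
  set.seed(77)
  # overcomplete hidden layer (L > N) so the system has many exact solutions
  X <- matrix(rnorm(6 * 2), 6, 2)
  y <- rep(c(1, -1), 3)
  m <- elmTrain(X, y, elmConfig(nHidden = 15, seed = 3))
  H <- hiddenOracle(m, X)
  beta <- m@outputWeights
  resid <- sqrt(sum((H %*% beta - y)^2))
  expect_lt(resid, 1e-8)                      # interpolates
  # any null-space perturbation keeps the residual but grows the norm
  ns <- svd(H, nv = 15)$v[, 7:15]
  for (j in seq_len(ncol(ns))) {
    alt <- beta + ns[, j]
    expect_lt(sqrt(sum((H %*% alt - y)^2)), 1e-6)
    expect_gt(sqrt(sum(alt^2)), sqrt(sum(beta^2)) - 1e-8)
  }
})

test_that("L = N hidden nodes interpolate distinct samples (zero training error)", {
  for (seed in 1:25) {
    set.seed(seed)
    X <- matrix(rnorm(8), 4, 2)
    y <- c(1, 1, -1, -1)
    m <- elmTrain(X, y, elmConfig(nHidden = 4, seed = seed))
    expect_equal(elmPredict(m, X)$labels, y)
  }
})

test_that("two linearly separable points are fit exactly", {
  X <- rbind(c(1, 0), c(-1, 0))
  m <- elmTrain(X, c(1, -1), elmConfig(nHidden = 20, seed = 1))
  expect_equal(elmPredict(m, X)$labels, c(1, -1))
})

test_that("prediction is a pure deterministic function of (model, X)", {
  ft <- separableTable(n = 10)
  X <- featureValues(ft)
  m1 <- elmTrain(X, featureLabels(ft), elmConfig(seed = 5))
  m2 <- elmTrain(X, featureLabels(ft), elmConfig(seed = 5))
  expect_identical(m1@outputWeights, m2@outputWeights)
  expect_identical(elmPredict(m1, X), elmPredict(m1, X))
  expect_identical(elmPredict(m1, X)$scores, elmPredict(m2, X)$scores)
})

test_that("a zero output vector scores 0 everywhere and predicts +1 under >=", {
  m <- elmTrain(matrix(rnorm(8), 4), c(1, 1, -1, -1), elmConfig(seed = 2))
  m@outputWeights <- rep(0, length(m@outputWeights))
  out <- elmPredict(m, matrix(rnorm(6), 3))
  expect_equal(out$scores, rep(0, 3))
  expect_equal(out$labels, rep(1, 3))
})

test_that("input validation rejects mismatched or degenerate input", {
  X <- matrix(rnorm(8), 4)
  expect_error(elmTrain(X, c(1, 1, 1, 1)), "class")
  expect_error(elmTrain(X, c(1, -1)), "label length")
  X[1] <- Inf
  expect_error(elmTrain(X, c(1, 1, -1, -1)), "finite")
  m <- elmTrain(matrix(rnorm(8), 4), c(1, 1, -1, -1))
  expect_error(elmPredict(m, matrix(rnorm(9), 3)), "dimension mismatch")
})

test_that("training stats: separable data trains to 100% with zero spread", {
  ft <- separableTable(n = 10, gap = 6)
  st <- repeatedInitTrainingStats(featureValues(ft), featureLabels(ft),
                                  elmConfig(nHidden = 20), nRepeats = 5)
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
})

test_that("training stats on label-free noise sit strictly between 50 and 100", {
  set.seed(42)
  X <- matrix(runif(110 * 10), 110, 10)
  y <- rep(c(1, -1), 55)
  st <- repeatedInitTrainingStats(X, y, elmConfig(nHidden = 20, seed = 9),
                                  nRepeats = 10)
  expect_gt(st$mean, 50)
  expect_lt(st$mean, 100)
  expect_error(repeatedInitTrainingStats(X, y, nRepeats = 1), "nRepeats")
})

test_that("training accuracy grows monotonically with hidden-layer width", {
  co <- normalizeMinMax(generateCohort(cohortSpec(
    nPatients = 20, nControls = 20, schema = standardSchema()[1:5, ],
    informativeIndices = 1:2, effectSize = 1, seed = 31)))
  X <- featureValues(co); y <- featureLabels(co)
  meanAcc <- vapply(c(1, 5, 20, 40), function(L) {
    repeatedInitTrainingStats(X, y, elmConfig(nHidden = L, seed = 100),
                              nRepeats = 30)$mean
  }, numeric(1))
  expect_true(all(diff(meanAcc) >= -1))   # 1-point Monte-Carlo slack
})

test_that("models survive a JSON round trip bit-for-bit in behavior", {
  ft <- separableTable(n = 8)
  m <- elmTrain(featureValues(ft), featureLabels(ft), elmConfig(seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  elmWrite(m, path)
  m2 <- elmRead(path)
  X <- matrix(rnorm(10), 5)
  expect_equal(elmPredict(m2, X)$scores, elmPredict(m, X)$scores,
               tolerance = 1e-12)
  expect_error(elmRead(withr::local_tempfile(lines = "{}")), "not a cortexELM")
})
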
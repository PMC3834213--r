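test_that("LOOCV runs one fold per subject and scores the held-out row", {
  ft <- separableTable(n = 10)
  res <- loocv(ft, 1:2, meanClassifier(), seed = 3)
  expect_length(res@foldScores, 10L)
  expect_length(res@foldPredictions, 10L)
  expect_equal(res@trueLabels, featureLabels(ft))
  expect_equal(res@testAcc, 100)
})

test_that("a constant +1 classifier scores 50% on balanced labels", {
  ft <- randomTable(n = 10, p = 3, seed = 5)
  res <- loocv(ft, 1:3, alwaysPositiveClassifier(), trainStats = FALSE)
  expect_equal(testAccuracy(res), 50)
})

test_that("fold isolation: the held-out subject's label cannot leak into its fold", {
  ft <- randomTable(n = 12, p = 4, seed = 9)
  resA <- loocv(ft, 1:4, elmClassifier(elmConfig(nHidden = 8)), seed = 11)
  # flip only the held-out subject's label: fold 3 trains on rows -3, whose
  # labels are unchanged, so its prediction must be bit-identical
  y1 <- featureLabels(ft); y1[3] <- -y1[3]
  ft1 <- FeatureTable(featureValues(ft), y1, subjectIds(ft),
                      schema = descriptors(ft))
  resC <- loocv(ft1, 1:4, elmClassifier(elmConfig(nHidden = 8)), seed = 11)
  expect_identical(resC@foldScores[3], resA@foldScores[3])
})

test_that("deterministic classifiers report fold-wise training statistics", {
  ft <- separableTable(n = 10, gap = 5)
  res <- loocv(ft, 1:2, svmClassifier(svmConfig("linear"), cost = 10))
  expect_equal(res@trainAccMean, 100)
  expect_equal(res@trainAccSd, 0)
  expect_error(loocv(ft, integer(0), meanClassifier()), "empty")
})

test_that("per-fold normalization keeps the held-out row out of the scaling", {
  ft <- randomTable(n = 8, p = 3, seed = 2)
  res <- loocv(ft, 1:3, meanClassifier(), perFoldNormalize = TRUE,
               trainStats = FALSE)
  expect_length(res@foldScores, 8L)
})

test_that("ROC endpoints, monotonicity and perfect separation", {
  rc <- rocCurve(c(3, 2, 1, 0), c(1, 1, -1, -1))
  expect_equal(auc(rc), 1)
  expect_equal(rc@tpr[1], 0); expect_equal(rc@fpr[1], 0)
  expect_equal(rc@tpr[length(rc@tpr)], 1)
  expect_equal(rc@fpr[length(rc@fpr)], 1)
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:20, 1)
    s <- sample(round(rnorm(n), 1))          # induces ties
    y <- sample(c(rep(1, 3), rep(-1, n - 3)))
    rc <- rocCurve(s, y)
    expect_true(all(diff(rc@tpr) >= 0))
    expect_true(all(diff(rc@fpr) >= 0))
  }
  expect_error(rocCurve(c(1, 2), c(1, 1)), "class")
})

test_that("AUC equals the tie-aware pairwise-comparison oracle exactly", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(6:25, 1)
    scores <- sample(round(rnorm(n), 1))
    labels <- c(rep(1, 4), rep(-1, n - 4))[sample(n)]
    expect_equal(auc(rocCurve(scores, labels)),
                 pairwiseAUC(scores, labels))
  }
})

test_that("AUC matches an independent ROC library on a spot check", {
  skip_if_not_installed("pROC")
  set.seed(10)
  scores <- rnorm(40)
  labels <- rep(c(1, -1), 20)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  mine <- auc(rocCurve(scores, labels))
  # pROC auto-orients toward AUC >= 0.5; compare orientation-free
  expect_equal(max(mine, 1 - mine), ref, tolerance = 1e-12)
})

test_that("permutation p-value follows the add-one estimator", {
  # strongly separable: observed beats every null draw
  co <- normalizeMinMax(generateCohort(cohortSpec(
    nPatients = 8, nControls = 8, schema = standardSchema()[1:4, ],
    informativeIndices = 1:2, effectSize = 4, seed = 13)))
  pr <- permutationTest(co, 1:2, meanClassifier(), nPerm = 19, seed = 2)
  expect_equal(pr@observedRate, 100)
  expect_equal(pValue(pr), 1 / 20)
  # constant classifier: every null rate ties the observed rate -> p = 1
  pr2 <- permutationTest(co, 1:2, alwaysPositiveClassifier(), nPerm = 9)
  expect_equal(pValue(pr2), 1)
  expect_length(pr2@nullRates, 9L)
})

test_that("paired comparison matches the textbook formula and handles degeneracy", {
  set.seed(3)
  a <- runif(12, 60, 90); b <- runif(12, 60, 90)
  mine <- pairedComparison(a, b)
  oracle <- pairedTOracle(a, b)
  expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(mine$pValue, oracle$pValue, tolerance = 1e-10)
  expect_false(mine$degenerate)
  ident <- pairedComparison(a, a)
  expect_equal(ident$statistic, 0); expect_equal(ident$pValue, 1)
  expect_true(ident$degenerate)
  const <- pairedComparison(a + 5, a)
  expect_true(const$degenerate)
  expect_equal(const$statistic, Inf)
  expect_error(pairedComparison(a, b[-1]), "length")
})

test_that("sample-size sweep draws balanced subsets and spans the grid", {
  co <- normalizeMinMax(generateCohort(cohortSpec(
    nPatients = 10, nControls = 10, schema = standardSchema()[1:4, ],
    informativeIndices = 1:2, effectSize = 2, seed = 21)))
  seen <- new.env(); seen$trainLabels <- list()
  recorder <- meanClassifier()
  innerFit <- recorder$fit
  recorder$fit <- function(X, y, seed) {
    seen$trainLabels[[length(seen$trainLabels) + 1L]] <- y
    innerFit(X, y, seed)
  }
  sw <- sampleSizeSweep(co, 1:2, list(ncm = recorder),
                        sizes = c(10, 20), seed = 4)
  expect_equal(sw$size, c(10, 20))
  expect_true(all(sw$testAcc >= 0 & sw$testAcc <= 100))
  # every LOOCV training split of a balanced size-s subset holds s/2 of one
  # class and s/2 - 1 of the other
  counts <- vapply(seen$trainLabels, function(y)
    abs(sum(y == 1) - sum(y == -1)), numeric(1))
  expect_true(all(counts == 1))
  expect_error(sampleSizeSweep(co, 1:2, list(ncm = meanClassifier()),
                               sizes = 15), "even")
  expect_error(sampleSizeSweep(co, 1:2, list(ncm = meanClassifier()),
                               sizes = 40), "exceeds")
})

test_that("sweep at the full cohort size reproduces the plain LOOCV result", {
  co <- normalizeMinMax(generateCohort(cohortSpec(
    nPatients = 8, nControls = 8, schema = standardSchema()[1:4, ],
    informativeIndices = 1:2, effectSize = 1.5, seed = 6)))
  sw <- sampleSizeSweep(co, 1:3, list(ncm = meanClassifier()), sizes = 16,
                        seed = 9)
  plain <- loocv(co, 1:3, meanClassifier())
  expect_equal(sw$testAcc, testAccuracy(plain))
})

test_that("LOOCV of the Bayes-style rule approaches the theoretical accuracy", {
  spec <- cohortSpec(nPatients = 200, nControls = 200,
                     schema = standardSchema()[1:6, ],
                     informativeIndices = 1:3, effectSize = 1,
                     withinRegionCorrelation = 0, seed = 17)
  co <- generateCohort(spec)
  # the true Bayes rule for this model: weight the informative features by
  # delta / sigma^2 (thickness scale constant 0.15), midpoint threshold
  sigma <- 0.15
  delta <- ifelse(1:6 %in% 1:3, 1 * sigma, 0)
  w <- delta / sigma^2
  thr <- sum(w * (2.5 + delta / 2))
  bayesRule <- list(name = "bayes", stochastic = FALSE,
    fit = function(X, y, seed) NULL,
    predict = function(fit, X) {
      s <- drop(X %*% w) - thr
      list(scores = s, labels = ifelse(s >= 0, 1, -1))
    })
  res <- loocv(co, 1:6, bayesRule, trainStats = FALSE)
  expect_lt(abs(testAccuracy(res) / 100 - theoreticalBayesAccuracy(spec)),
            0.03)
})
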
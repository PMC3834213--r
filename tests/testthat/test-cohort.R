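test_that("generated cohorts have the requested shape and labels", {
  co <- generateCohort(cohortSpec(nPatients = 55, nControls = 55, seed = 7))
  v <- featureValues(co)
  expect_equal(dim(v), c(110L, 340L))
  expect_equal(sum(featureLabels(co) == 1), 55L)
  expect_equal(sum(featureLabels(co) == -1), 55L)
  expect_true(all(is.finite(v)))
})

test_that("generation is a pure function of the seed", {
  s <- cohortSpec(nPatients = 8, nControls = 8, seed = 123)
  expect_identical(featureValues(generateCohort(s)),
                   featureValues(generateCohort(s)))
  s2 <- cohortSpec(nPatients = 8, nControls = 8, seed = 124)
  expect_false(identical(featureValues(generateCohort(s)),
                         featureValues(generateCohort(s2))))
  # and it leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generateCohort(s)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("column moments and within-parcel correlation match the model", {
  spec <- cohortSpec(nPatients = 1000, nControls = 1000, effectSize = 0,
                     withinRegionCorrelation = 0.3, seed = 42)
  v <- featureValues(generateCohort(spec))
  sch <- standardSchema()
  # thickness columns: location 2.5 mm, sd 0.15 (controls model defaults)
  th <- v[, sch$measure == "thickness"]
  expect_equal(mean(colMeans(th)), 2.5, tolerance = 0.01)
  expect_equal(mean(apply(th, 2, sd)), 0.15, tolerance = 0.01)
  # the five measures of one parcel are exchangeably correlated at rho
  leftCuneus <- which(sch$hemisphere == "left" & sch$region == "cuneus")
  cors <- cor(v[, leftCuneus])
  offdiag <- cors[upper.tri(cors)]
  expect_lt(abs(mean(offdiag) - 0.3), 0.04)
  # different parcels are uncorrelated
  expect_lt(abs(cor(v[, 4], v[, 5])), 0.08)
})

test_that("informative features carry the configured standardized shift", {
  spec <- cohortSpec(nPatients = 1000, nControls = 1000, effectSize = 1.5,
                     informativeIndices = c(72, 140), seed = 11)
  v <- featureValues(generateCohort(spec))
  y <- featureLabels(generateCohort(spec))
  d <- (mean(v[y == 1, 72]) - mean(v[y == -1, 72])) / sd(v[y == -1, 72])
  expect_equal(d, 1.5, tolerance = 0.12)
  # non-informative features show no shift
  d0 <- (mean(v[y == 1, 10]) - mean(v[y == -1, 10])) / sd(v[y == -1, 10])
  expect_lt(abs(d0), 0.15)
})

test_that("spec validation rejects impossible parameters", {
  expect_error(cohortSpec(withinRegionCorrelation = 1), "Correlation")
  expect_error(cohortSpec(withinRegionCorrelation = -0.1), "Correlation")
  expect_error(cohortSpec(noiseSd = 0), "noiseSd")
  expect_error(cohortSpec(effectSize = -1), "effectSize")
  expect_error(cohortSpec(nPatients = 0), "at least one subject")
  expect_error(cohortSpec(informativeIndices = 341), "outside the schema")
})

test_that("Bayes accuracy: closed form matches its definition and limits", {
  # indistinguishable classes
  expect_equal(theoreticalBayesAccuracy(cohortSpec(effectSize = 0)), 0.5)
  # one informative feature, independent noise, d = 2 -> Phi(1)
  spec1 <- cohortSpec(informativeIndices = 72, effectSize = 2,
                      withinRegionCorrelation = 0)
  expect_equal(theoreticalBayesAccuracy(spec1), pnorm(1), tolerance = 1e-12)
  # non-decreasing in effect size
  accs <- vapply(c(0, 0.5, 1, 1.5, 2, 3), function(d)
    theoreticalBayesAccuracy(cohortSpec(effectSize = d)), numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("Monte-Carlo accuracy of the true Bayes rule matches the closed form", {
  # small schema (10 singleton parcels) keeps the check fast
  sch <- standardSchema()[1:10, ]
  spec <- cohortSpec(nPatients = 3000, nControls = 3000, schema = sch,
                     informativeIndices = c(1, 2, 3), effectSize = 1,
                     withinRegionCorrelation = 0.4, noiseSd = 1, seed = 5)
  co <- generateCohort(spec)
  v <- featureValues(co); y <- featureLabels(co)
  # Bayes rule for equal-covariance Gaussians, built from the true model:
  # singleton parcels => diagonal covariance; delta = d * sd on informative
  sdCols <- 0.15                       # thickness scale constant
  delta <- ifelse(1:10 %in% c(1, 2, 3), 1 * sdCols, 0)
  w <- delta / sdCols^2
  # use the model's true means, not the sample's
  muP <- 2.5 + delta; muC <- rep(2.5, 10)
  scores <- v %*% w - sum(w * (muP + muC) / 2)
  acc <- mean(ifelse(scores >= 0, 1, -1) == y)
  expect_equal(acc, theoreticalBayesAccuracy(spec), tolerance = 0.015)
})
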
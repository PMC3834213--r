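## Synthetic two-class cortical cohorts.
##
## Class-conditional model: equal-covariance multivariate Gaussian. Within
## each (hemisphere, region) parcel the five morphometric measures share an
## exchangeable correlation rho; parcels are independent. Patients receive a
## mean shift of effectSize * noiseSd (a standardized difference d) on the
## informative features. Values are then mapped into plausible per-measure
## ranges by fixed affine constants (thickness ~ mm, area ~ mm^2, ...); the
## affine map cancels out of the Fisher score, the min-max normalization and
## the Bayes accuracy, so it only serves fixture realism.

.measureLoc <- c(thickness = 2.5, surface_area = 2500, volume = 6000,
                 folding_index = 15, curvature = 0.13)
.measureScale <- c(thickness = 0.15, surface_area = 300, volume = 800,
                   folding_index = 3, curvature = 0.02)

#' Default informative feature set for synthetic cohorts
#'
#' Eleven features spanning surface area, volume and folding index of
#' occipital, temporal, frontal and insular parcels — the measures and
#' regions most often reported as discriminative in cortical-morphometry
#' ADHD studies — so that default synthetic cohorts put their signal where a
#' real cohort plausibly would.
#'
#' @return sorted integer vector of length 11.
#' @export
defaultInformativeIndices <- function() {
  sort(c(72L, 271L, 238L, 140L, 119L, 84L, 227L, 272L, 148L, 218L, 101L))
}

#' Specification of a synthetic two-class cortical cohort
#'
#' @param nPatients,nControls class sizes (default 55 + 55, the cohort size
#'   the pipeline targets).
#' @param schema feature descriptors, default [standardSchema()].
#' @param informativeIndices features carrying a class mean shift (default
#'   [defaultInformativeIndices()]).
#' @param effectSize standardized mean difference d per informative feature
#'   (unitless, default 1.0).
#' @param withinRegionCorrelation exchangeable correlation among the
#'   measures of one (hemisphere, region) parcel, in [0, 1) (default 0.3).
#' @param noiseSd within-class standard deviation on the latent scale
#'   (> 0, default 1).
#' @param seed integer RNG seed.
#' @return a `CohortSpec` (classed list).
#' @export
cohortSpec <- function(nPatients = 55L, nControls = 55L,
                       schema = standardSchema(),
                       informativeIndices = defaultInformativeIndices(),
                       effectSize = 1.0, withinRegionCorrelation = 0.3,
                       noiseSd = 1.0, seed = 1L) {
  if (nPatients < 1L || nControls < 1L)
    stop("need at least one subject per class")
  if (!all(informativeIndices %in% seq_len(nrow(schema))))
    stop("informativeIndices outside the schema")
  if (effectSize < 0) stop("effectSize must be >= 0")
  if (withinRegionCorrelation < 0 || withinRegionCorrelation >= 1)
    stop("withinRegionCorrelation must lie in [0, 1)")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  structure(list(nPatients = as.integer(nPatients),
                 nControls = as.integer(nControls),
                 schema = schema,
                 informativeIndices = sort(as.integer(informativeIndices)),
                 effectSize = effectSize,
                 withinRegionCorrelation = withinRegionCorrelation,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "CohortSpec")
}

## parcels = independent covariance blocks: features sharing a
## (hemisphere, region); features without region metadata are singletons.
.covBlocks <- function(schema) {
  key <- ifelse(is.na(schema$region), paste0("f", schema$index),
                paste(schema$hemisphere, schema$region))
  split(seq_len(nrow(schema)), key)
}

#' Generate a synthetic cohort as a FeatureTable
#'
#' Draws `nPatients + nControls` subjects from the class-conditional
#' Gaussian model described in [cohortSpec()]; patients are labelled +1 and
#' listed first. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohortSpec()].
#' @return an un-normalized [FeatureTable-class].
#' @examples
#' ft <- generateCohort(cohortSpec(nPatients = 5, nControls = 5))
#' table(featureLabels(ft))
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$nPatients + spec$nControls
  p <- nrow(spec$schema)
  rho <- spec$withinRegionCorrelation
  blocks <- .covBlocks(spec$schema)
  z <- .withSeed(spec$seed, {
    zz <- matrix(stats::rnorm(n * p), n, p)
    for (b in blocks) {
      k <- length(b)
      if (k > 1L && rho > 0) {
        R <- matrix(rho, k, k); diag(R) <- 1
        zz[, b] <- zz[, b, drop = FALSE] %*% chol(R)
      }
    }
    zz
  })
  z <- z * spec$noiseSd
  shift <- spec$effectSize * spec$noiseSd
  z[seq_len(spec$nPatients), spec$informativeIndices] <-
    z[seq_len(spec$nPatients), spec$informativeIndices, drop = FALSE] + shift
  loc <- .measureLoc[spec$schema$measure]
  scl <- .measureScale[spec$schema$measure]
  loc[is.na(loc)] <- 0; scl[is.na(scl)] <- 1
  vals <- sweep(sweep(z, 2L, scl, "*"), 2L, loc, "+")
  colnames(vals) <- spec$schema$name
  labels <- c(rep(1, spec$nPatients), rep(-1, spec$nControls))
  ids <- c(sprintf("P%03d", seq_len(spec$nPatients)),
           sprintf("C%03d", seq_len(spec$nControls)))
  FeatureTable(vals, labels, ids, schema = spec$schema, normalized = FALSE)
}

#' Closed-form Bayes-optimal accuracy of a synthetic cohort model
#'
#' For the equal-covariance Gaussian model the Bayes rule is linear and its
#' accuracy (balanced classes) is Phi(Delta / 2), with Delta the Mahalanobis
#' distance between the class means. The block covariance structure makes
#' Delta computable parcel by parcel:
#' Delta^2 = sum_b delta_b' Sigma_b^{-1} delta_b.
#'
#' @param spec a [cohortSpec()].
#' @return accuracy in [0.5, 1].
#' @examples
#' theoreticalBayesAccuracy(cohortSpec(effectSize = 0))   # 0.5
#' @export
theoreticalBayesAccuracy <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  rho <- spec$withinRegionCorrelation
  sd2 <- spec$noiseSd^2
  shift <- spec$effectSize * spec$noiseSd
  d2 <- 0
  for (b in .covBlocks(spec$schema)) {
    delta <- ifelse(b %in% spec$informativeIndices, shift, 0)
    if (!any(delta != 0)) next
    k <- length(b)
    R <- matrix(rho, k, k); diag(R) <- 1
    d2 <- d2 + drop(crossprod(delta, solve(sd2 * R, delta)))
  }
  stats::pnorm(sqrt(d2) / 2)
}
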
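## Classifier contracts
##
## Evaluation routines are classifier-agnostic: a classifier is a list with
##   $name        display name
##   $stochastic  TRUE when training depends on a random initialization
##   $fit(X, y, seed) -> fitted object
##   $predict(fit, X) -> list(scores = numeric, labels = +1/-1)
## so LOOCV, permutation tests and the pipeline work identically for the
## extreme learning machine, the SVM baselines, and test stubs.

#' Classifier contract for the extreme learning machine
#'
#' @param config an [elmConfig()]; the `seed` field is superseded by the
#'   per-fold seed supplied by the evaluation protocol.
#' @return classifier contract list (see [loocv()]).
#' @export
elmClassifier <- function(config = elmConfig()) {
  list(name = "ELM", stochastic = TRUE,
       fit = function(X, y, seed) {
         cfg <- config; cfg$seed <- as.integer(seed)
         elmTrain(X, y, cfg)
       },
       predict = function(fit, X) elmPredict(fit, X))
}

#' Classifier contract for an SVM with fixed hyperparameters
#'
#' @param config an [svmConfig()] (provides the kernel).
#' @param cost,gamma hyperparameters, e.g. chosen by [svmGridSearch()].
#' @return classifier contract list (see [loocv()]).
#' @export
svmClassifier <- function(config = svmConfig(), cost = 1, gamma = NA) {
  nm <- if (config$kernel == "linear") "SVM-Linear" else "SVM-RBF"
  list(name = nm, stochastic = FALSE,
       fit = function(X, y, seed) .fitSvm(X, y, config$kernel, cost, gamma),
       predict = function(fit, X) {
         s <- .svmScores(fit, X)
         list(scores = s, labels = ifelse(s >= 0, 1, -1))
       })
}

#' Leave-one-out cross-validation of a classifier on a feature subset
#'
#' One fold per subject: the classifier is trained on the other N - 1
#' subjects (stochastic classifiers get an independent seed per fold, all
#' derived from `seed`) and scored on the held-out subject. Testing accuracy
#' is the percentage of correctly classified held-out subjects. Training
#' accuracy is reported as mean +/- SD over repeated random initializations
#' on the full subset for stochastic classifiers, and fold-wise
#' (resubstitution accuracy per training split) for deterministic ones.
#'
#' @param table a [FeatureTable-class] with >= 2 subjects per class.
#' @param subset integer feature indices to use (non-empty).
#' @param classifier a classifier contract ([elmClassifier()],
#'   [svmClassifier()] or compatible).
#' @param seed master seed for per-fold substreams.
#' @param edId experimental-dataset id recorded in the result (default 0).
#' @param trainStats compute training-accuracy statistics (default TRUE;
#'   disable inside tight loops such as permutation tests).
#' @param nRepeats random initializations for stochastic training stats.
#' @param perFoldNormalize min-max normalize each training fold and apply
#'   the fold's affine map to the held-out subject (leakage-free variant;
#'   default FALSE, matching the whole-cohort normalization protocol).
#' @return an [EvaluationResult-class].
#' @export
loocv <- function(table, subset, classifier, seed = 1L, edId = 0L,
                  trainStats = TRUE, nRepeats = 20L,
                  perFoldNormalize = FALSE) {
  if (!length(subset)) stop("feature subset is empty")
  y <- featureLabels(table)
  .checkBinaryLabels(y, minPerClass = 2L)
  v <- featureValues(table)[, subset, drop = FALSE]
  n <- nrow(v)
  foldSeeds <- .seedStream(seed, n + 1L)
  scores <- numeric(n)
  preds <- numeric(n)
  foldTrainAcc <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- v[-i, , drop = FALSE]
    Xte <- v[i, , drop = FALSE]
    if (perFoldNormalize) {
      lo <- apply(Xtr, 2L, min); hi <- apply(Xtr, 2L, max)
      span <- hi - lo; span[span == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, lo, "-"), 2L, span, "/")
      Xte <- sweep(sweep(Xte, 2L, lo, "-"), 2L, span, "/")
    }
    fit <- classifier$fit(Xtr, y[-i], foldSeeds[i])
    out <- classifier$predict(fit, Xte)
    scores[i] <- out$scores[1L]
    preds[i] <- out$labels[1L]
    if (trainStats && !classifier$stochastic)
      foldTrainAcc[i] <- .accuracyPct(classifier$predict(fit, Xtr)$labels,
                                      y[-i])
  }
  if (trainStats) {
    if (classifier$stochastic) {
      repSeeds <- foldSeeds[n + 1L] + seq_len(nRepeats) - 1L
      accs <- vapply(repSeeds, function(s)
        .accuracyPct(classifier$predict(classifier$fit(v, y, s), v)$labels, y),
        numeric(1))
      trMean <- mean(accs); trSd <- stats::sd(accs)
    } else {
      trMean <- mean(foldTrainAcc); trSd <- stats::sd(foldTrainAcc)
    }
  } else {
    trMean <- NA_real_; trSd <- NA_real_
  }
  new("EvaluationResult", edId = as.integer(edId),
      featureSubset = as.integer(subset), classifier = classifier$name,
      trainAccMean = trMean, trainAccSd = trSd,
      testAcc = .accuracyPct(preds, y),
      foldScores = scores, foldPredictions = preds, trueLabels = y)
}

#' @rdname loocv
#' @param x an [EvaluationResult-class].
#' @param ... unused.
#' @export
setMethod("testAccuracy", "EvaluationResult", function(x, ...) x@testAcc)

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult [%s, ED %d, %d features]\n",
              object@classifier, object@edId, length(object@featureSubset)))
  if (!is.na(object@trainAccMean))
    cat(sprintf("  train acc: %.2f%% +/- %.2f\n", object@trainAccMean,
                object@trainAccSd))
  cat(sprintf("  LOOCV test acc: %.2f%%\n", object@testAcc))
})

#' Receiver-operating-characteristic curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (descending,
#' starting above the maximum so the curve begins at (0, 0) and ends at
#' (1, 1)); tied scores move the curve diagonally in one step. The AUC is
#' the trapezoid area, which equals the tie-aware Mann-Whitney statistic
#' P(score+ > score-) + 0.5 P(score+ = score-).
#'
#' @param scores continuous decision scores.
#' @param labels +1/-1 class labels (both classes present).
#' @return a [ROCCurve-class]; `auc(x)` extracts the area.
#' @examples
#' auc(rocCurve(c(3, 2, 1, 0), c(1, 1, -1, -1)))   # 1
#' @export
rocCurve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  .checkBinaryLabels(labels)
  if (!all(is.finite(scores))) stop("non-finite scores")
  nPos <- sum(labels == 1); nNeg <- sum(labels == -1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / nPos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == -1) / nNeg,
                numeric(1))
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCCurve", thresholds = thr, tpr = tpr, fpr = fpr, auc = a)
}

#' @rdname rocCurve
#' @param x a [ROCCurve-class].
#' @param ... unused.
#' @export
setMethod("auc", "ROCCurve", function(x, ...) x@auc)

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d threshold(s), AUC = %.4f\n",
              length(object@thresholds), object@auc))
})

#' Permutation test of a classifier's generalization rate
#'
#' The observed statistic is the LOOCV testing accuracy on the true labels.
#' Each permutation uniformly reshuffles the full label vector (seeded)
#' before the LOOCV loop and recomputes the rate, building the null
#' distribution of the generalization rate under "no label-feature
#' relationship". The p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + nPerm), which is never exactly 0.
#'
#' @param table,subset,classifier as [loocv()].
#' @param nPerm number of permutations (default 1000; increase to 10000 for
#'   publication-grade runs).
#' @param seed master seed (drives fold seeds and the label shuffles).
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(table, subset, classifier, nPerm = 1000L,
                            seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  seeds <- .seedStream(seed + 1L, nPerm)
  observed <- testAccuracy(loocv(table, subset, classifier, seed = seed,
                                 trainStats = FALSE))
  v <- featureValues(table)
  y <- featureLabels(table)
  ids <- subjectIds(table)
  sch <- descriptors(table)
  nullRates <- vapply(seq_len(nPerm), function(b) {
    yPerm <- .withSeed(seeds[b], sample(y))
    tPerm <- FeatureTable(v, yPerm, ids, schema = sch,
                          normalized = isNormalized(table))
    testAccuracy(loocv(tPerm, subset, classifier, seed = seeds[b],
                       trainStats = FALSE))
  }, numeric(1))
  p <- (1 + sum(nullRates >= observed)) / (1 + nPerm)
  new("PermutationResult", observedRate = observed, nullRates = nullRates,
      pValue = p)
}

#' @rdname permutationTest
#' @param x a [PermutationResult-class].
#' @param ... unused.
#' @export
setMethod("pValue", "PermutationResult", function(x, ...) x@pValue)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: observed rate %.2f%%, %d permutations\n",
              object@observedRate, length(object@nullRates)))
  cat(sprintf("  p = %.4g\n", object@pValue))
})

#' Paired comparison of two classifiers' per-dataset accuracies
#'
#' Two-sided paired t-test on matched accuracy vectors (one entry per
#' experimental dataset). When the paired differences have zero variance the
#' t statistic is degenerate: the result is flagged `degenerate = TRUE`,
#' with t = 0, p = 1 for identical vectors and t = +/-Inf, p = 0 for a
#' constant non-zero difference.
#'
#' @param accA,accB numeric accuracy vectors (%) of equal length >= 2.
#' @return list with `statistic`, `pValue`, `df`, `meanDifference`,
#'   `degenerate`.
#' @export
pairedComparison <- function(accA, accB) {
  if (length(accA) != length(accB)) stop("accuracy vectors differ in length")
  if (length(accA) < 2L) stop("need at least 2 paired observations")
  d <- accA - accB
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(statistic = if (m == 0) 0 else sign(m) * Inf,
                pValue = if (m == 0) 1 else 0,
                df = length(d) - 1L, meanDifference = m, degenerate = TRUE))
  }
  tt <- stats::t.test(accA, accB, paired = TRUE)
  list(statistic = unname(tt$statistic), pValue = tt$p.value,
       df = unname(tt$parameter), meanDifference = unname(tt$estimate),
       degenerate = FALSE)
}

#' Classification accuracy as a function of cohort size
#'
#' For each requested size, draws a balanced random subsample (size/2
#' patients and size/2 controls, seeded) and runs [loocv()] for every
#' classifier, mapping how training and testing accuracy respond to sample
#' size. Requesting the full cohort size reproduces the plain LOOCV result.
#'
#' @param table a balanced [FeatureTable-class].
#' @param subset feature indices to use.
#' @param classifiers named list of classifier contracts.
#' @param sizes even subject counts, each <= the cohort size
#'   (default 10, 20, ..., 110 capped at the cohort size).
#' @param seed master seed.
#' @param nRepeats independent subsample draws per size (default 1).
#' @return data.frame with columns `size`, `repeatId`, `classifier`,
#'   `trainAccMean`, `trainAccSd`, `testAcc`.
#' @export
sampleSizeSweep <- function(table, subset, classifiers,
                            sizes = seq(10L, 110L, by = 10L), seed = 1L,
                            nRepeats = 1L) {
  y <- featureLabels(table)
  nPos <- sum(y == 1); nNeg <- sum(y == -1)
  if (nPos != nNeg) stop("sampleSizeSweep expects a balanced cohort")
  if (any(sizes %% 2 != 0)) stop("sizes must be even (balanced halves)")
  if (any(sizes > length(y))) stop("a requested size exceeds the cohort")
  drawSeeds <- matrix(.seedStream(seed, length(sizes) * nRepeats),
                      length(sizes), nRepeats)
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    for (r in seq_len(nRepeats)) {
      half <- size %/% 2L
      idx <- .withSeed(drawSeeds[si, r],
                       sort(c(sample(which(y == 1), half),
                              sample(which(y == -1), half))))
      sub <- subsetFeatures(table, subjects = idx)
      for (nm in names(classifiers)) {
        res <- loocv(sub, subset, classifiers[[nm]],
                     seed = drawSeeds[si, r])
        rows[[length(rows) + 1L]] <-
          data.frame(size = size, repeatId = r, classifier = res@classifier,
                     trainAccMean = res@trainAccMean,
                     trainAccSd = res@trainAccSd, testAcc = res@testAcc)
      }
    }
  }
  do.call(rbind, rows)
}
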
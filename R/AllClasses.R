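#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' FeatureTable: subjects x cortical-features matrix with class labels
#'
#' `FeatureTable` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' the single assay `"features"` stores features as rows and subjects as
#' columns (Bioconductor convention), `rowData` carries one
#' feature descriptor per row (`index`, `measure`, `hemisphere`, `region`),
#' and `colData` carries `subject_id` and the diagnosis `label` coded
#' +1 (patient) / -1 (control). The metadata flag `normalized` records
#' whether columns have been min-max scaled to [0, 1].
#'
#' Use [featureValues()] to obtain the subjects x features matrix most
#' formulas are written against; [labels()][featureLabels()] and
#' [subjectIds()] access the per-subject annotation.
#'
#' @slot .. see SummarizedExperiment; no additional slots.
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

.validFeatureTable <- function(object) {
  msg <- NULL
  if (!("features" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'features' is missing")
  else {
    v <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(v)) msg <- c(msg, "feature values must be numeric")
    else if (length(v) && !all(is.finite(v)))
      msg <- c(msg, "feature values must all be finite")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "label") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'subject_id' and 'label'")
  else {
    if (anyDuplicated(cd$subject_id))
      msg <- c(msg, "duplicate subject ids")
    if (length(cd$label) && !all(cd$label %in% c(-1, 1)))
      msg <- c(msg, "labels must be coded +1/-1")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("index", "measure", "hemisphere", "region") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry feature descriptors")
  if (!is.logical(S4Vectors::metadata(object)$normalized))
    msg <- c(msg, "metadata$normalized must be a logical flag")
  if (is.null(msg)) TRUE else msg
}
setValidity("FeatureTable", .validFeatureTable)

#' Fisher-score ranking of the features of a cohort
#'
#' @slot scores numeric vector of per-feature F-scores (>= 0, possibly Inf).
#' @slot order integer permutation: feature indices in descending score
#'   order, ties broken by ascending feature index.
#' @slot infinite logical: TRUE where the within-class variance vanished while
#'   the between-class separation did not (score flagged +Inf).
#' @exportClass FScoreRanking
setClass("FScoreRanking",
  representation(scores = "numeric", order = "integer", infinite = "logical"))

setValidity("FScoreRanking", function(object) {
  if (length(object@order) != length(object@scores))
    return("order and scores lengths differ")
  if (length(object@order) &&
      !identical(sort(object@order), seq_along(object@scores)))
    return("order is not a permutation of the feature indices")
  s <- object@scores[object@order]
  if (length(s) > 1L && any(diff(s) > 0)) return("order is not descending")
  TRUE
})

#' Trace of a greedy sequential forward selection run
#'
#' @slot steps data.frame with one row per greedy step: `feature` (the index
#'   added) and `criterion` (criterion value of the augmented subset).
#' @slot selectedAtBest integer vector: the earliest prefix of `steps`
#'   attaining the maximum criterion value.
#' @exportClass SFSTrace
setClass("SFSTrace",
  representation(steps = "data.frame", selectedAtBest = "integer"))

#' Trained extreme learning machine
#'
#' A single-hidden-layer feedforward network whose input weights and biases
#' are random and whose output weights are the minimum-norm least-squares
#' solution beta = pinv(H) T.
#'
#' @slot inputWeights numeric matrix [nHidden x nFeatures].
#' @slot hiddenBiases numeric vector [nHidden].
#' @slot outputWeights numeric vector beta [nHidden].
#' @slot config list: the `elmConfig()` used for training.
#' @slot nFeatures integer.
#' @exportClass ELMModel
setClass("ELMModel",
  representation(inputWeights = "matrix", hiddenBiases = "numeric",
                 outputWeights = "numeric", config = "list",
                 nFeatures = "integer"))

setValidity("ELMModel", function(object) {
  L <- nrow(object@inputWeights)
  if (ncol(object@inputWeights) != object@nFeatures)
    return("inputWeights columns must equal nFeatures")
  if (length(object@hiddenBiases) != L || length(object@outputWeights) != L)
    return("bias/output-weight length must equal the number of hidden nodes")
  if (!all(is.finite(object@inputWeights)) ||
      !all(is.finite(object@hiddenBiases)) ||
      !all(is.finite(object@outputWeights)))
    return("model parameters must be finite")
  TRUE
})

#' Leave-one-out cross-validation result for one classifier on one subset
#'
#' @slot edId integer experimental-dataset identifier (0 when free-standing).
#' @slot featureSubset integer feature indices evaluated.
#' @slot classifier character classifier name.
#' @slot trainAccMean,trainAccSd training accuracy (%) mean and SD
#'   (over random initialisations for the ELM, over folds for deterministic
#'   classifiers).
#' @slot testAcc LOOCV testing accuracy (%).
#' @slot foldScores,foldPredictions per-fold held-out decision scores and
#'   predicted labels (one per subject).
#' @slot trueLabels the cohort labels, fold order.
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(edId = "integer", featureSubset = "integer",
                 classifier = "character",
                 trainAccMean = "numeric", trainAccSd = "numeric",
                 testAcc = "numeric",
                 foldScores = "numeric", foldPredictions = "numeric",
                 trueLabels = "numeric"))

setValidity("EvaluationResult", function(object) {
  n <- length(object@trueLabels)
  if (length(object@foldScores) != n || length(object@foldPredictions) != n)
    return("one held-out prediction per subject is required")
  accs <- c(object@trainAccMean, object@testAcc)
  if (any(accs < 0 | accs > 100, na.rm = TRUE))
    return("accuracies must lie in [0, 100]")
  TRUE
})

#' Receiver-operating-characteristic curve
#'
#' @slot thresholds descending decision thresholds (+Inf first).
#' @slot tpr,fpr true/false positive rates along the sweep, starting at
#'   (0, 0) and ending at (1, 1).
#' @slot auc area under the curve (trapezoid; equals the tie-aware
#'   Mann-Whitney pairwise statistic).
#' @exportClass ROCCurve
setClass("ROCCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric"))

setValidity("ROCCurve", function(object) {
  n <- length(object@thresholds)
  if (length(object@tpr) != n || length(object@fpr) != n)
    return("thresholds, tpr and fpr must have equal length")
  if (any(diff(object@tpr) < 0) || any(diff(object@fpr) < 0))
    return("tpr and fpr must be non-decreasing as the threshold decreases")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' Permutation-test result for a classifier's generalization rate
#'
#' @slot observedRate LOOCV testing accuracy (%) on the true labels.
#' @slot nullRates generalization rates (%) on label-permuted data.
#' @slot pValue add-one estimator (1 + #\{null >= observed\}) / (1 + N).
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(observedRate = "numeric", nullRates = "numeric",
                 pValue = "numeric"))

setValidity("PermutationResult", function(object) {
  p <- object@pValue
  n <- length(object@nullRates)
  expect <- (1 + sum(object@nullRates >= object@observedRate)) / (1 + n)
  if (abs(p - expect) > 1e-12) return("pValue inconsistent with nullRates")
  if (p <= 0 || p > 1) return("pValue must lie in (0, 1]")
  TRUE
})
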
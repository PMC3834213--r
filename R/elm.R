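#' Extreme learning machine configuration
#'
#' @param nHidden number of hidden nodes L (default 20).
#' @param activation hidden activation; only the logistic sigmoid
#'   `g(u) = 1/(1+exp(-u))` is currently provided.
#' @param weightRange,biasRange intervals from which input weights and
#'   hidden biases are drawn uniformly (default [-1, 1]).
#' @param seed integer seed for the random hidden layer.
#' @param decisionThreshold decision threshold on the network output
#'   (default 0: score >= 0 predicts +1).
#' @return classed list `ELMConfig`.
#' @export
elmConfig <- function(nHidden = 20L, activation = c("sigmoid"),
                      weightRange = c(-1, 1), biasRange = c(-1, 1),
                      seed = 1L, decisionThreshold = 0) {
  activation <- match.arg(activation)
  if (nHidden < 1L) stop("nHidden must be >= 1")
  stopifnot(length(weightRange) == 2L, length(biasRange) == 2L,
            weightRange[1] < weightRange[2], biasRange[1] < biasRange[2])
  structure(list(nHidden = as.integer(nHidden), activation = activation,
                 weightRange = as.numeric(weightRange),
                 biasRange = as.numeric(biasRange),
                 seed = as.integer(seed),
                 decisionThreshold = as.numeric(decisionThreshold)),
            class = "ELMConfig")
}

.sigmoid <- function(u) 1 / (1 + exp(-u))

## Moore-Penrose pseudoinverse solve: minimum-norm least-squares solution of
## H beta = t via SVD, singular values below max(dim(H)) * eps * sigma_max
## treated as zero.
.pinvSolve <- function(H, t) {
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  if (!any(keep)) return(numeric(ncol(H)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], t)) / sv$d[keep]))
}

.hiddenLayer <- function(model, X) {
  .sigmoid(X %*% t(model@inputWeights) +
             matrix(model@hiddenBiases, nrow(X), length(model@hiddenBiases),
                    byrow = TRUE))
}

#' Train an extreme learning machine
#'
#' Input weights `W` and hidden biases `b` are drawn uniformly at random
#' (seeded); the hidden output matrix is `H[k, j] = g(w_j . x_k + b_j)` with
#' g the logistic sigmoid, and the single output node's weights are solved
#' in closed form as the minimum-norm least-squares solution
#' `beta = H^+ T` (Moore-Penrose pseudoinverse, SVD), with targets `T = y`
#' coded +1/-1. No iterative optimization and no hyperparameters beyond the
#' hidden-layer width are involved; the only stochasticity is the random
#' hidden layer.
#'
#' @param X numeric matrix [N x d] of (normalized) features, N >= 2, both
#'   classes present.
#' @param y labels +1/-1.
#' @param config an [elmConfig()].
#' @return an [ELMModel-class].
#' @examples
#' X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
#' m <- elmTrain(X, c(-1, -1, 1, 1), elmConfig(seed = 7))
#' elmPredict(m, X)$labels
#' @export
elmTrain <- function(X, y, config = elmConfig()) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in the feature matrix")
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  .checkBinaryLabels(y)
  if (length(y) != nrow(X)) stop("label length must match rows of X")
  L <- config$nHidden
  d <- ncol(X)
  wr <- config$weightRange; br <- config$biasRange
  init <- .withSeed(config$seed, list(
    W = matrix(stats::runif(L * d, wr[1], wr[2]), L, d),
    b = stats::runif(L, br[1], br[2])))
  model <- new("ELMModel", inputWeights = init$W, hiddenBiases = init$b,
               outputWeights = numeric(L), config = unclass(config),
               nFeatures = as.integer(d))
  H <- .hiddenLayer(model, X)
  model@outputWeights <- .pinvSolve(H, as.numeric(y))
  validObject(model)
  model
}

#' Predict with a trained extreme learning machine
#'
#' @param model an [ELMModel-class].
#' @param X numeric matrix [M x d], d matching the training dimension.
#' @return list with `scores` (continuous network outputs) and `labels`
#'   (+1 where score >= the configured threshold, else -1).
#' @export
elmPredict <- function(model, X) {
  stopifnot(is(model, "ELMModel"))
  X <- as.matrix(X)
  if (ncol(X) != model@nFeatures)
    stop("feature dimension mismatch: model expects ", model@nFeatures,
         ", got ", ncol(X))
  scores <- drop(.hiddenLayer(model, X) %*% model@outputWeights)
  thr <- model@config$decisionThreshold
  list(scores = scores, labels = ifelse(scores >= thr, 1, -1))
}

#' Training-accuracy statistics over repeated random initializations
#'
#' The ELM's only stochasticity is its random hidden layer, so training
#' accuracy is summarized as mean and sample SD of the resubstitution
#' accuracy over `nRepeats` models trained with seeds
#' `config$seed, config$seed + 1, ...`.
#'
#' @param X,y,config as [elmTrain()].
#' @param nRepeats number of random initializations (>= 2, default 20).
#' @return list with `mean` and `sd`, both in percent.
#' @export
repeatedInitTrainingStats <- function(X, y, config = elmConfig(),
                                      nRepeats = 20L) {
  if (nRepeats < 2L) stop("nRepeats must be >= 2")
  accs <- vapply(seq_len(nRepeats) - 1L, function(k) {
    cfg <- config; cfg$seed <- config$seed + k
    m <- elmTrain(X, y, cfg)
    .accuracyPct(elmPredict(m, X)$labels, y)
  }, numeric(1))
  list(mean = mean(accs), sd = stats::sd(accs))
}

setMethod("show", "ELMModel", function(object) {
  cat("ELMModel: single-hidden-layer feedforward network\n")
  cat("  hidden nodes:", length(object@hiddenBiases),
      " input features:", object@nFeatures, "\n")
  cat("  |beta|_2 =", format(sqrt(sum(object@outputWeights^2)), digits = 4),
      " seed:", object@config$seed, "\n")
})

#' Save / load an ELM model as JSON text
#'
#' The format stores the input weights, hidden biases, output weights,
#' the training configuration and the feature count.
#'
#' @param model an [ELMModel-class].
#' @param path file path.
#' @return `elmWrite` returns `invisible(path)`; `elmRead` the model.
#' @export
elmWrite <- function(model, path) {
  stopifnot(is(model, "ELMModel"))
  obj <- list(format = "cortexELM/elm-model/1",
              nFeatures = model@nFeatures,
              inputWeights = model@inputWeights,
              hiddenBiases = model@hiddenBiases,
              outputWeights = model@outputWeights,
              config = model@config)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname elmWrite
#' @export
elmRead <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (!identical(obj$format, "cortexELM/elm-model/1"))
    stop("not a cortexELM model file: ", path)
  cfg <- obj$config
  cfg$nHidden <- as.integer(cfg$nHidden)
  cfg$seed <- as.integer(cfg$seed)
  m <- new("ELMModel",
           inputWeights = matrix(obj$inputWeights,
                                 nrow = length(obj$hiddenBiases)),
           hiddenBiases = as.numeric(obj$hiddenBiases),
           outputWeights = as.numeric(obj$outputWeights),
           config = cfg, nFeatures = as.integer(obj$nFeatures))
  validObject(m)
  m
}
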
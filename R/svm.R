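#' Support-vector-machine baseline configuration
#'
#' Default hyperparameter grids follow the standard LIBSVM practical guide:
#' exponentially growing sequences C in 2^(-5), 2^(-3), ..., 2^15 and
#' (RBF only) gamma in 2^(-15), 2^(-13), ..., 2^3.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param costGrid candidate C values (> 0).
#' @param gammaGrid candidate gamma values (> 0; RBF only).
#' @param innerCvFolds folds of the stratified inner cross-validation used
#'   by the grid search (default 5).
#' @param seed integer seed for fold assignment.
#' @return classed list `SVMConfig`.
#' @export
svmConfig <- function(kernel = c("linear", "rbf"),
                      costGrid = 2^seq(-5, 15, by = 2),
                      gammaGrid = 2^seq(-15, 3, by = 2),
                      innerCvFolds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!length(costGrid) || any(costGrid <= 0))
    stop("costGrid must be non-empty and positive")
  if (kernel == "rbf" && (!length(gammaGrid) || any(gammaGrid <= 0)))
    stop("gammaGrid must be non-empty and positive")
  structure(list(kernel = kernel, costGrid = as.numeric(sort(costGrid)),
                 gammaGrid = as.numeric(sort(gammaGrid)),
                 innerCvFolds = as.integer(innerCvFolds),
                 seed = as.integer(seed)),
            class = "SVMConfig")
}

## Stratified fold ids: each class spread as evenly as possible.
.stratifiedFolds <- function(y, k, seed) {
  folds <- integer(length(y))
  .withSeed(seed, {
    for (cls in c(1, -1)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

.fitSvm <- function(X, y, kernel, cost, gamma) {
  # factor levels fixed so +1 (patient) is the positive decision direction
  yf <- factor(y, levels = c(1, -1))
  if (kernel == "linear")
    e1071::svm(X, yf, type = "C-classification", kernel = "linear",
               cost = cost, scale = FALSE)
  else
    e1071::svm(X, yf, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
}

.svmScores <- function(fit, X) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- unname(drop(attr(pred, "decision.values")))
  # LIBSVM orients the decision value toward the first of the two training
  # classes; flip when that was the control class.
  if (!grepl("^1/", colnames(attr(pred, "decision.values"))[1])) dv <- -dv
  dv
}

#' Grid search for SVM hyperparameters by stratified inner cross-validation
#'
#' Every grid point is evaluated by `innerCvFolds`-fold stratified
#' cross-validation on the supplied (training) data only; the point with the
#' best mean accuracy is returned, ties resolved toward the smallest C and
#' then the smallest gamma. Test data must not be passed in: the search
#' never sees it.
#'
#' @param X numeric training matrix, `y` labels +1/-1.
#' @param y labels.
#' @param config an [svmConfig()].
#' @return list with `cost`, `gamma` (`NA` for the linear kernel) and
#'   `table`, a data.frame of all grid points with their inner-CV accuracy
#'   (%).
#' @export
svmGridSearch <- function(X, y, config = svmConfig()) {
  X <- as.matrix(X)
  .checkBinaryLabels(y, minPerClass = 2L)
  k <- min(config$innerCvFolds, sum(y == 1), sum(y == -1))
  folds <- .stratifiedFolds(y, k, config$seed)
  grid <- if (config$kernel == "linear")
    data.frame(cost = config$costGrid, gamma = NA_real_)
  else
    expand.grid(cost = config$costGrid, gamma = config$gammaGrid,
                KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- .fitSvm(X[tr, , drop = FALSE], y[tr], config$kernel,
                     grid$cost[i], grid$gamma[i])
      pred <- .svmScores(fit, X[!tr, , drop = FALSE]) >= 0
      correct <- correct + sum(ifelse(pred, 1, -1) == y[!tr])
    }
    100 * correct / length(y)
  }, numeric(1))
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1L], ]
  list(cost = best$cost, gamma = best$gamma, table = grid)
}

#' Train an SVM and score test data
#'
#' Thin, deterministic wrapper around the LIBSVM solver (via e1071):
#' maximum-margin fit with the chosen kernel and hyperparameters, continuous
#' decision-function scores oriented so that positive means the patient
#' class, and labels thresholded at 0.
#'
#' @param XTrain,yTrain training data (+1/-1 labels).
#' @param XTest matrix to score.
#' @param config an [svmConfig()] (provides the kernel).
#' @param cost,gamma hyperparameters, e.g. from [svmGridSearch()].
#' @return list with `scores` and `labels` for `XTest`, plus `model`.
#' @export
svmTrainPredict <- function(XTrain, yTrain, XTest, config = svmConfig(),
                            cost = 1, gamma = NA) {
  XTrain <- as.matrix(XTrain); XTest <- as.matrix(XTest)
  .checkBinaryLabels(yTrain)
  if (ncol(XTest) != ncol(XTrain)) stop("feature dimension mismatch")
  fit <- .fitSvm(XTrain, yTrain, config$kernel, cost, gamma)
  scores <- .svmScores(fit, XTest)
  list(scores = scores, labels = ifelse(scores >= 0, 1, -1), model = fit)
}
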
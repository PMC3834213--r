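#' Fisher-score (F-score) ranking of features
#'
#' For feature i with positive-class values x+ (n+ subjects), negative-class
#' values x- (n-) and whole-cohort mean xbar_i:
#' \deqn{F(i) = \frac{(\bar x^+_i - \bar x_i)^2 + (\bar x^-_i - \bar x_i)^2}
#'   {\frac{1}{n^+-1}\sum_k (x^+_{k,i}-\bar x^+_i)^2 +
#'    \frac{1}{n^--1}\sum_k (x^-_{k,i}-\bar x^-_i)^2}}
#' The numerator measures between-class separation, the denominator pooled
#' within-class sample variance; larger F marks a more discriminative
#' feature. Degenerate cases: 0/0 (feature constant within and between
#' classes) scores 0; positive/0 (classes separated with zero within-class
#' variance) scores +Inf and is flagged. F is invariant under positive
#' affine per-feature transforms, so ranking before or after min-max
#' normalization is identical up to ties.
#'
#' @param table a [FeatureTable-class] with >= 2 subjects in each class.
#' @return an [FScoreRanking-class]; `featureOrder()` gives feature indices
#'   in descending score order, ties broken by ascending index.
#' @examples
#' ft <- FeatureTable(cbind(f = c(0.8, 1.0, 0.0, 0.2)),
#'                    labels = c(1, 1, -1, -1))
#' featureScores(fScore(ft))   # 8
#' @export
fScore <- function(table) {
  y <- featureLabels(table)
  .checkBinaryLabels(y, minPerClass = 2L)
  v <- featureValues(table)
  pos <- v[y == 1, , drop = FALSE]
  neg <- v[y == -1, , drop = FALSE]
  mAll <- colMeans(v)
  mPos <- colMeans(pos)
  mNeg <- colMeans(neg)
  num <- (mPos - mAll)^2 + (mNeg - mAll)^2
  den <- apply(pos, 2L, stats::var) + apply(neg, 2L, stats::var)
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  scores <- unname(scores)
  ord <- order(-scores, seq_along(scores))
  new("FScoreRanking", scores = scores, order = as.integer(ord),
      infinite = is.infinite(scores) & scores > 0)
}

#' @rdname FScoreRanking-accessors
#' @export
setMethod("featureScores", "FScoreRanking", function(x, ...) x@scores)

#' Accessors for FScoreRanking
#' @param x an [FScoreRanking-class].
#' @param ... unused.
#' @name FScoreRanking-accessors
NULL

#' @rdname FScoreRanking-accessors
#' @export
setMethod("featureOrder", "FScoreRanking", function(x, ...) x@order)

setMethod("show", "FScoreRanking", function(object) {
  cat("FScoreRanking over", length(object@scores), "features\n")
  k <- min(5L, length(object@order))
  cat("  top", k, "indices:", paste(object@order[seq_len(k)], collapse = ", "),
      "\n")
  if (any(object@infinite))
    cat(" ", sum(object@infinite), "feature(s) flagged +Inf\n")
})

#' Nested experimental datasets from a feature ranking
#'
#' Experimental dataset k (`ED_k`) is the top-k ranked features: each
#' feature combined with all preceding (better-ranked) features, giving
#' `kMax` nested prefixes.
#'
#' @param ranking an [FScoreRanking-class].
#' @param kMax number of prefixes (1 <= kMax <= number of features).
#' @return list of integer vectors; element k has length k and is a prefix
#'   of element k+1.
#' @export
cumulativeDatasets <- function(ranking, kMax) {
  stopifnot(is(ranking, "FScoreRanking"))
  n <- length(ranking@order)
  if (kMax < 1L) stop("kMax must be >= 1")
  if (kMax > n) stop("kMax exceeds the number of features")
  lapply(seq_len(kMax), function(k) ranking@order[seq_len(k)])
}
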
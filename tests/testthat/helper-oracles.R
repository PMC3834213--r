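## Independent oracles, deliberately written as naive loops so they share no
## code path with the package implementation.

# Fisher score, elementwise: between-class separation over pooled
# within-class sample variance, whole-cohort mean in the numerator.
bruteFScore <- function(values, labels) {
  p <- ncol(values)
  out <- numeric(p)
  for (i in seq_len(p)) {
    xp <- values[labels == 1, i]
    xn <- values[labels == -1, i]
    xall <- values[, i]
    num <- (mean(xp) - mean(xall))^2 + (mean(xn) - mean(xall))^2
    sp <- sum((xp - mean(xp))^2) / (length(xp) - 1)
    sn <- sum((xn - mean(xn))^2) / (length(xn) - 1)
    den <- sp + sn
    out[i] <- if (den > 0) num / den else if (num > 0) Inf else 0
  }
  out
}

# Greedy forward selection by exhaustive per-step enumeration over a
# criterion lookup table keyed by the sorted subset.
subsetKey <- function(s) paste(sort(s), collapse = ",")

greedyOracle <- function(pool, critTable, maxSteps = length(pool)) {
  chosen <- integer(0)
  remaining <- sort(pool)
  path <- integer(0)
  crits <- numeric(0)
  for (step in seq_len(min(maxSteps, length(pool)))) {
    bestVal <- -Inf; bestFeat <- NA_integer_
    for (f in remaining) {           # ascending order -> ties keep lowest
      v <- critTable[[subsetKey(c(chosen, f))]]
      if (v > bestVal) { bestVal <- v; bestFeat <- f }
    }
    chosen <- c(chosen, bestFeat)
    path <- c(path, bestFeat)
    crits <- c(crits, bestVal)
    remaining <- setdiff(remaining, bestFeat)
  }
  list(path = path, criteria = crits,
       best = path[seq_len(which.max(crits))])
}

# Tie-aware Mann-Whitney AUC by explicit pairwise comparison.
pairwiseAUC <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Dense SVD least-squares oracle: builds the Moore-Penrose pseudoinverse
# explicitly (V D^+ U') with the conventional max(dim) * eps * sigma_max
# cutoff and multiplies it out.
svdPinvOracle <- function(H, y) {
  s <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(s$d)
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  pinv <- s$v %*% diag(dinv, length(dinv)) %*% t(s$u)
  drop(pinv %*% y)
}

# Textbook paired t statistic and two-sided p.
pairedTOracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, pValue = 2 * pt(-abs(t), df = n - 1))
}

# Logistic-sigmoid hidden layer, recomputed from the model's slots.
hiddenOracle <- function(model, X) {
  W <- model@inputWeights
  b <- model@hiddenBiases
  H <- matrix(0, nrow(X), nrow(W))
  for (k in seq_len(nrow(X)))
    for (j in seq_len(nrow(W)))
      H[k, j] <- 1 / (1 + exp(-(sum(W[j, ] * X[k, ]) + b[j])))
  H
}
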
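#' Greedy sequential forward selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature whose
#' addition maximizes the criterion of the augmented subset (ties broken by
#' the lowest feature index), until `maxSteps` features have been added or
#' the pool is exhausted. The run does not stop at the first decline: the
#' criterion curve is explored to the end and `selectedFeatures()` returns
#' the earliest prefix attaining the maximum criterion value, so a later
#' recovery after a local dip is not lost.
#'
#' @param candidatePool integer feature indices to select from (non-empty).
#' @param criterion function(integer subset) -> single number; larger is
#'   better. In the pipeline this is the LOOCV testing accuracy of the
#'   configured classifier on the candidate subset, but any deterministic
#'   evaluator works.
#' @param maxSteps maximum subset size (default: the whole pool).
#' @return an [SFSTrace-class]; `selectedFeatures()` gives the best prefix,
#'   `x@steps` the full greedy path with criterion values.
#' @examples
#' crit <- function(s) -length(s)          # strictly decreasing
#' selectedFeatures(sfs(c(3, 1, 2), crit)) # a single feature
#' @export
sfs <- function(candidatePool, criterion, maxSteps = length(candidatePool)) {
  pool <- as.integer(candidatePool)
  if (!length(pool)) stop("candidate pool is empty")
  if (anyDuplicated(pool)) stop("candidate pool has duplicate indices")
  maxSteps <- min(as.integer(maxSteps), length(pool))
  if (maxSteps < 1L) stop("maxSteps must be >= 1")
  chosen <- integer(0)
  remaining <- pool
  steps <- data.frame(feature = integer(0), criterion = numeric(0))
  for (step in seq_len(maxSteps)) {
    vals <- vapply(remaining, function(f) criterion(c(chosen, f)), numeric(1))
    best <- which(vals == max(vals))
    pick <- best[which.min(remaining[best])]   # tie -> lowest feature index
    chosen <- c(chosen, remaining[pick])
    steps <- rbind(steps, data.frame(feature = remaining[pick],
                                     criterion = vals[pick]))
    remaining <- remaining[-pick]
  }
  bestLen <- which.max(steps$criterion)        # earliest maximizing prefix
  new("SFSTrace", steps = steps,
      selectedAtBest = as.integer(chosen[seq_len(bestLen)]))
}

#' @rdname sfs
#' @param x an [SFSTrace-class].
#' @param ... unused.
#' @export
setMethod("selectedFeatures", "SFSTrace", function(x, ...) x@selectedAtBest)

setMethod("show", "SFSTrace", function(object) {
  cat("SFSTrace:", nrow(object@steps), "greedy step(s)\n")
  cat("  best prefix (", length(object@selectedAtBest), " features): ",
      paste(object@selectedAtBest, collapse = ", "), "\n", sep = "")
  cat("  best criterion:", max(object@steps$criterion), "\n")
})
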
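## Seed hygiene: all randomness inside the package runs under a saved/
## restored RNG state, so calling package functions never perturbs the
## caller's random stream and every result is a pure function of the
## explicit seed arguments.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Independent substreams: a deterministic vector of n child seeds derived
## from one master seed (all < 2^31), used to reseed per-fold / per-repeat
## work so that folds are exchangeable yet the whole run is reproducible.
.seedStream <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.accuracyPct <- function(predicted, truth) 100 * mean(predicted == truth)

.checkBinaryLabels <- function(y, minPerClass = 1L) {
  if (!all(y %in% c(-1, 1))) stop("labels must be coded +1/-1")
  if (sum(y == 1) < minPerClass || sum(y == -1) < minPerClass)
    stop("each class needs at least ", minPerClass, " subject(s)")
  invisible(y)
}
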
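## Programmatic fixtures: everything is generated at test time.

# A FreeSurfer-style per-hemisphere parcellation summary table.
# Values are deterministic functions of (region rank, hemisphere offset) so
# placement tests can predict exactly what lands where.
aparcValue <- function(col, i, base) {
  switch(col,
    SurfArea = 1000 + 10 * i + base,
    GrayVol  = 3000 + 20 * i + base,
    ThickAvg = 2 + i / 100 + base / 1000,
    MeanCurv = 0.100 + i / 1000 + base / 1e5,
    FoldInd  = 10 + i + base / 10,
    stop("unknown column ", col))
}

writeAparcFixture <- function(path, base = 0, dropRegions = character(0),
                              regions = corticalRegions()) {
  keep <- setdiff(regions, dropRegions)
  lines <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    "# anatomy_type surface",
    paste("# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg",
          "ThickStd MeanCurv GausCurv FoldInd CurvInd"))
  for (r in keep) {
    i <- match(r, regions)
    lines <- c(lines, paste(
      r, 4000 + i,
      aparcValue("SurfArea", i, base), aparcValue("GrayVol", i, base),
      sprintf("%.3f", aparcValue("ThickAvg", i, base)), "0.500",
      sprintf("%.4f", aparcValue("MeanCurv", i, base)), "0.020",
      sprintf("%.1f", aparcValue("FoldInd", i, base)), "1.0"))
  }
  writeLines(lines, path)
  invisible(path)
}

# Small random feature table with balanced labels.
randomTable <- function(n = 12, p = 6, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("f%d", seq_len(p))))
  FeatureTable(v, labels = rep(c(1, -1), each = n / 2))
}

# A clearly separable two-feature cohort.
separableTable <- function(n = 12, gap = 4, seed = 1) {
  set.seed(seed)
  half <- n / 2
  v <- rbind(matrix(rnorm(half * 2, mean = gap / 2, sd = 0.5), half),
             matrix(rnorm(half * 2, mean = -gap / 2, sd = 0.5), half))
  colnames(v) <- c("f1", "f2")
  FeatureTable(v, labels = rep(c(1, -1), each = half))
}

# Classifier contract stubs.
alwaysPositiveClassifier <- function() {
  list(name = "always+1", stochastic = FALSE,
       fit = function(X, y, seed) NULL,
       predict = function(fit, X)
         list(scores = rep(1, nrow(X)), labels = rep(1, nrow(X))))
}

# Nearest-class-mean contract: deterministic, learns something real.
meanClassifier <- function() {
  list(name = "ncm", stochastic = FALSE,
       fit = function(X, y, seed)
         list(mp = colMeans(X[y == 1, , drop = FALSE]),
              mn = colMeans(X[y == -1, , drop = FALSE])),
       predict = function(fit, X) {
         s <- apply(X, 1, function(r)
           sum((r - fit$mn)^2) - sum((r - fit$mp)^2))
         list(scores = s, labels = ifelse(s >= 0, 1, -1))
       })
}
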
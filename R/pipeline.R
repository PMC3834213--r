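#' Pipeline configuration
#'
#' Bundles everything the full flow needs: which classifiers to run, their
#' configurations, the feature-selection stage sizes and the master seed.
#' Stage order is fixed: min-max normalization, Fisher-score ranking,
#' cumulative experimental datasets, sequential forward selection over the
#' top-ranked pool, final validation (ROC/AUC + permutation test).
#'
#' @param classifiers subset of `c("elm", "svm_linear", "svm_rbf")`; the
#'   first entry is the primary classifier (drives the SFS criterion and
#'   the permutation test).
#' @param elm an [elmConfig()].
#' @param svmLinear,svmRbf [svmConfig()]s for the two baselines.
#' @param kMax number of cumulative experimental datasets for the ranking
#'   curve (default 340).
#' @param sfsPoolSize SFS candidate pool: the top `sfsPoolSize` ranked
#'   features (default 46, the span within which the accuracy curves peak).
#' @param sfsMaxSteps maximum SFS subset size (default 19).
#' @param nPerm permutations for the significance test (default 1000).
#' @param normalize min-max normalize the cohort before ranking
#'   (default TRUE).
#' @param svmTuning `"once"`: grid-search each experimental dataset once on
#'   the full data before LOOCV; `"nested"`: re-tune inside every training
#'   fold (slower, leakage-free).
#' @param seed master seed; mandatory for every stochastic step.
#' @return classed list `PipelineConfig`.
#' @export
pipelineConfig <- function(classifiers = c("elm", "svm_linear", "svm_rbf"),
                           elm = elmConfig(), svmLinear = svmConfig("linear"),
                           svmRbf = svmConfig("rbf"), kMax = 340L,
                           sfsPoolSize = 46L, sfsMaxSteps = 19L,
                           nPerm = 1000L, normalize = TRUE,
                           svmTuning = c("once", "nested"), seed = 1L) {
  if (!length(classifiers)) stop("at least one classifier is required")
  classifiers <- match.arg(classifiers, c("elm", "svm_linear", "svm_rbf"),
                           several.ok = TRUE)
  structure(list(classifiers = classifiers, elm = elm,
                 svmLinear = svmLinear, svmRbf = svmRbf,
                 kMax = as.integer(kMax),
                 sfsPoolSize = as.integer(sfsPoolSize),
                 sfsMaxSteps = as.integer(sfsMaxSteps),
                 nPerm = as.integer(nPerm), normalize = isTRUE(normalize),
                 svmTuning = match.arg(svmTuning), seed = as.integer(seed)),
            class = "PipelineConfig")
}

## Build the classifier contract for one named classifier on one feature
## subset; SVMs get their hyperparameters grid-searched once on the subset
## ("once" tuning), mirroring a per-experimental-dataset tune.
.makeContract <- function(name, X, y, config) {
  switch(name,
    elm = elmClassifier(config$elm),
    svm_linear = {
      gs <- svmGridSearch(X, y, config$svmLinear)
      svmClassifier(config$svmLinear, cost = gs$cost)
    },
    svm_rbf = {
      gs <- svmGridSearch(X, y, config$svmRbf)
      svmClassifier(config$svmRbf, cost = gs$cost, gamma = gs$gamma)
    },
    stop("unknown classifier '", name, "'"))
}

.prepTable <- function(table, config) {
  if (config$normalize && !isNormalized(table)) normalizeMinMax(table)
  else table
}

.fmtAcc <- function(m, s) {
  ifelse(is.na(m), "-", sprintf("%.2f\u00b1%.2f", m, s))
}

## One report row per experimental dataset, Table-2/3 shape:
## ED no., added feature [index, measure, region], train acc +/- SD per
## classifier, test acc per classifier.
.edReport <- function(results, added, schema) {
  classifiers <- names(results[[1L]])
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    row <- data.frame(ED = k,
                      Feature = featureLabel(added[k], schema),
                      stringsAsFactors = FALSE)
    for (nm in classifiers) {
      row[[paste0("TrainAcc.", r[[nm]]@classifier)]] <-
        .fmtAcc(r[[nm]]@trainAccMean, r[[nm]]@trainAccSd)
      row[[paste0("TestAcc.", r[[nm]]@classifier)]] <-
        sprintf("%.2f", r[[nm]]@testAcc)
    }
    row
  })
  do.call(rbind, rows)
}

.reportText <- function(df, title) {
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(c) max(nchar(as.character(c)), 0L),
                        integer(1)))
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  lines <- c(title,
             paste(mapply(pad, names(df), widths), collapse = "  "),
             vapply(seq_len(nrow(df)), function(i)
               paste(mapply(pad, df[i, ], widths), collapse = "  "),
               character(1)))
  paste0(sub(" +$", "", lines), collapse = "\n")
}

.provenance <- function(config, stage) {
  list(stage = stage, package = "cortexELM",
       version = as.character(utils::packageVersion("cortexELM")),
       rVersion = R.version.string,
       seed = config$seed,
       config = config[setdiff(names(config), "seed")])
}

#' Stage 1: Fisher-score ranking curve over cumulative experimental datasets
#'
#' Normalizes the cohort, ranks all features by Fisher score, builds the
#' nested experimental datasets ED_1 .. ED_kMax (top-k features) and runs
#' LOOCV for every configured classifier on every ED.
#'
#' @param table a [FeatureTable-class].
#' @param config a [pipelineConfig()].
#' @param verbose print per-ED progress lines.
#' @return list with `ranking` ([FScoreRanking-class]), `results` (list of
#'   per-ED named lists of [EvaluationResult-class]), `report` (data.frame),
#'   `reportText` (fixed-width text table with best-ED markers),
#'   `bestEd` (named integer: best ED per classifier) and `provenance`.
#' @export
runFscoreCurve <- function(table, config = pipelineConfig(), verbose = FALSE) {
  table <- .prepTable(table, config)
  ranking <- fScore(table)
  kMax <- min(config$kMax, length(featureOrder(ranking)))
  eds <- cumulativeDatasets(ranking, kMax)
  v <- featureValues(table)
  y <- featureLabels(table)
  edSeeds <- .seedStream(config$seed, kMax)
  results <- vector("list", kMax)
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(kMax)) {
    subset <- eds[[k]]
    res <- list()
    for (nm in config$classifiers) {
      contract <- .makeContract(nm, v[, subset, drop = FALSE], y, config)
      res[[nm]] <- loocv(table, subset, contract, seed = edSeeds[k],
                         edId = k)
    }
    results[[k]] <- res
    if (verbose)
      message(sprintf("ED %d/%d: %s", k, kMax,
                      paste(sprintf("%s %.2f%%",
                                    vapply(res, slot, "", "classifier"),
                                    vapply(res, testAccuracy, 0)),
                            collapse = ", ")))
  }
  added <- featureOrder(ranking)[seq_len(kMax)]
  report <- .edReport(results, added, descriptors(table))
  bestEd <- vapply(config$classifiers, function(nm)
    which.max(vapply(results, function(r) testAccuracy(r[[nm]]), 0)),
    integer(1))
  for (nm in config$classifiers) {
    col <- paste0("TestAcc.", results[[1L]][[nm]]@classifier)
    report[[col]][bestEd[nm]] <- paste0("*", report[[col]][bestEd[nm]])
  }
  list(ranking = ranking, results = results, report = report,
       reportText = .reportText(report,
         "Cumulative experimental datasets (Fisher-score order)"),
       bestEd = bestEd,
       elapsedSec = proc.time()[["elapsed"]] - t0,
       provenance = .provenance(config, "fscore_curve"))
}

#' Stage 2: sequential forward selection over the top-ranked pool
#'
#' Runs greedy SFS on the top `sfsPoolSize` Fisher-ranked features using the
#' LOOCV testing accuracy of the primary (first configured) classifier as
#' the selection criterion, then evaluates every configured classifier on
#' each step's subset for the report.
#'
#' @param table a [FeatureTable-class].
#' @param config a [pipelineConfig()].
#' @param ranking an [FScoreRanking-class] (e.g. from [runFscoreCurve()]);
#'   computed from `table` when missing.
#' @param verbose print per-step progress lines.
#' @return list with `trace` ([SFSTrace-class]), `results`, `report`,
#'   `reportText`, `selected` (best feature subset, forwarded to the final
#'   validation) and `provenance`.
#' @export
runSfsStage <- function(table, config = pipelineConfig(), ranking = NULL,
                        verbose = FALSE) {
  table <- .prepTable(table, config)
  if (is.null(ranking)) ranking <- fScore(table)
  poolSize <- min(config$sfsPoolSize, length(featureOrder(ranking)))
  pool <- featureOrder(ranking)[seq_len(poolSize)]
  v <- featureValues(table)
  y <- featureLabels(table)
  primary <- config$classifiers[1L]
  criterion <- function(subset) {
    contract <- .makeContract(primary, v[, subset, drop = FALSE], y, config)
    testAccuracy(loocv(table, subset, contract, seed = config$seed,
                       trainStats = FALSE))
  }
  trace <- sfs(pool, criterion, maxSteps = config$sfsMaxSteps)
  stepSeeds <- .seedStream(config$seed + 1L, nrow(trace@steps))
  results <- lapply(seq_len(nrow(trace@steps)), function(k) {
    subset <- trace@steps$feature[seq_len(k)]
    res <- list()
    for (nm in config$classifiers) {
      contract <- .makeContract(nm, v[, subset, drop = FALSE], y, config)
      res[[nm]] <- loocv(table, subset, contract, seed = stepSeeds[k],
                         edId = k)
    }
    if (verbose)
      message(sprintf("SFS step %d: feature %d", k, trace@steps$feature[k]))
    res
  })
  report <- .edReport(results, trace@steps$feature, descriptors(table))
  list(trace = trace, results = results, report = report,
       reportText = .reportText(report,
         "Sequential forward selection (greedy, LOOCV criterion)"),
       selected = selectedFeatures(trace),
       provenance = .provenance(config, "sfs"))
}

#' Stage 3: final validation of a selected feature subset
#'
#' Per classifier: LOOCV held-out decision scores, ROC curve and AUC.
#' For the primary classifier additionally a permutation test of the
#' generalization rate with `config$nPerm` label shuffles.
#'
#' @param table a [FeatureTable-class].
#' @param subset selected feature indices (non-empty), e.g.
#'   `runSfsStage(...)$selected`.
#' @param config a [pipelineConfig()].
#' @return list with `evaluations`, `roc` (named list of
#'   [ROCCurve-class]), `auc` (named numeric), `permutation`
#'   ([PermutationResult-class] for the primary classifier), `features`
#'   (data.frame of the subset with index/measure/region labels),
#'   `reportText` and `provenance`.
#' @export
runFinalValidation <- function(table, subset, config = pipelineConfig()) {
  if (!length(subset)) stop("selected feature subset is empty")
  table <- .prepTable(table, config)
  v <- featureValues(table)
  y <- featureLabels(table)
  evals <- list(); rocs <- list()
  for (nm in config$classifiers) {
    contract <- .makeContract(nm, v[, subset, drop = FALSE], y, config)
    ev <- loocv(table, subset, contract, seed = config$seed)
    evals[[nm]] <- ev
    rocs[[nm]] <- rocCurve(ev@foldScores, y)
  }
  primary <- config$classifiers[1L]
  contract <- .makeContract(primary, v[, subset, drop = FALSE], y, config)
  perm <- permutationTest(table, subset, contract, nPerm = config$nPerm,
                          seed = config$seed)
  sch <- descriptors(table)
  feats <- data.frame(index = subset, label = featureLabel(subset, sch),
                      stringsAsFactors = FALSE)
  aucs <- vapply(rocs, auc, numeric(1))
  lines <- c("Final validation of the selected feature subset",
             paste("features:", paste(feats$label, collapse = " ")),
             vapply(names(evals), function(nm)
               sprintf("%s: LOOCV acc %.2f%%, AUC %.4f",
                       evals[[nm]]@classifier, evals[[nm]]@testAcc,
                       aucs[[nm]]), character(1)),
             sprintf("permutation test (%s, %d shuffles): p = %.4g",
                     evals[[primary]]@classifier, config$nPerm,
                     pValue(perm)))
  list(evaluations = evals, roc = rocs, auc = aucs, permutation = perm,
       features = feats, reportText = paste(lines, collapse = "\n"),
       provenance = .provenance(config, "final_validation"))
}

#' Write a stage's machine-readable provenance record
#'
#' @param result a list returned by a `run*` stage (with a `provenance`
#'   element).
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
writeProvenance <- function(result, path) {
  writeLines(jsonlite::toJSON(result$provenance, auto_unbox = TRUE,
                              digits = NA, force = TRUE), path)
  invisible(path)
}
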
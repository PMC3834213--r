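#' Construct a FeatureTable from a subjects x features matrix
#'
#' @param values numeric matrix, one row per subject, one column per feature.
#' @param labels numeric vector of +1 (patient) / -1 (control), one per
#'   subject.
#' @param subjectIds character subject identifiers (unique); defaults to
#'   `S1..Sn`.
#' @param schema descriptor DataFrame as returned by [standardSchema()];
#'   when `NULL`, the standard schema is attached if the column count is 340
#'   and column names (if any) match it, otherwise generic descriptors are
#'   built from the column names.
#' @param normalized logical, whether columns are already min-max scaled.
#' @return a [FeatureTable-class] object.
#' @examples
#' ft <- FeatureTable(matrix(rnorm(12), 3), labels = c(1, 1, -1))
#' dim(featureValues(ft))
#' @export
FeatureTable <- function(values, labels, subjectIds = NULL, schema = NULL,
                         normalized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  n <- nrow(values)
  if (length(labels) != n)
    stop("need one label per subject (", n, " subjects, ",
         length(labels), " labels)")
  if (is.null(subjectIds)) subjectIds <- sprintf("S%d", seq_len(n))
  if (is.null(schema)) {
    std <- standardSchema()
    cn <- colnames(values)
    schema <- if (ncol(values) == nrow(std) &&
                  (is.null(cn) || identical(cn, std$name))) std
              else .genericSchema(if (is.null(cn))
                sprintf("feature_%d", seq_len(ncol(values))) else cn)
  }
  if (nrow(schema) != ncol(values))
    stop("schema has ", nrow(schema), " descriptors but the table has ",
         ncol(values), " feature columns")
  assay <- t(values)
  dimnames(assay) <- list(schema$name, subjectIds)
  se <- SummarizedExperiment(
    assays = list(features = assay),
    rowData = schema,
    colData = DataFrame(subject_id = as.character(subjectIds),
                        label = as.numeric(labels),
                        row.names = subjectIds),
    metadata = list(normalized = isTRUE(normalized)))
  out <- new("FeatureTable", se)
  validObject(out)
  out
}

#' Accessors for FeatureTable
#'
#' `featureValues()` returns the subjects x features matrix;
#' `featureLabels()` the +1/-1 diagnosis vector; `subjectIds()` the subject
#' identifiers; `descriptors()` the per-feature descriptor DataFrame;
#' `isNormalized()` the min-max normalization flag.
#'
#' @param x a [FeatureTable-class].
#' @param ... unused.
#' @name FeatureTable-accessors
NULL

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureValues", "FeatureTable", function(x, ...)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname FeatureTable-accessors
#' @export
setMethod("featureLabels", "FeatureTable", function(x, ...)
  as.numeric(SummarizedExperiment::colData(x)$label))

#' @rdname FeatureTable-accessors
#' @export
setMethod("subjectIds", "FeatureTable", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$subject_id))

#' @rdname FeatureTable-accessors
#' @export
setMethod("descriptors", "FeatureTable", function(x, ...)
  SummarizedExperiment::rowData(x))

#' @rdname FeatureTable-accessors
#' @export
setMethod("isNormalized", "FeatureTable", function(x, ...)
  isTRUE(S4Vectors::metadata(x)$normalized))

setMethod("show", "FeatureTable", function(object) {
  lab <- featureLabels(object)
  cat("FeatureTable:", ncol(object), "subjects x", nrow(object),
      "cortical features\n")
  cat("  patients (+1):", sum(lab == 1), "  controls (-1):",
      sum(lab == -1), "\n")
  cat("  normalized to [0,1]:", isNormalized(object), "\n")
})

#' Min-max normalize every feature column to [0, 1]
#'
#' Each column x is mapped to (x - min(x)) / (max(x) - min(x)) over the whole
#' cohort, the normalization step that precedes feature ranking in the
#' pipeline. Constant columns map to all zeros (they carry no class
#' information; their Fisher score is 0 either way). The input object is not
#' modified. Idempotent on its own output.
#'
#' Normalizing over the whole cohort before cross-validation mirrors the
#' published protocol; for leakage-sensitivity studies normalize each
#' training fold instead by passing `perFold = TRUE` to [loocv()].
#'
#' @param x an un-normalized [FeatureTable-class] with >= 2 subjects.
#' @param ... unused.
#' @return a normalized [FeatureTable-class].
#' @examples
#' ft <- FeatureTable(cbind(a = c(2, 4, 6)), labels = c(1, 1, -1))
#' featureValues(normalizeMinMax(ft))   # 0, 0.5, 1
#' @rdname normalizeMinMax
#' @export
setMethod("normalizeMinMax", "FeatureTable", function(x, ...) {
  v <- featureValues(x)
  if (nrow(v) < 2L)
    stop("min-max normalization needs at least 2 subjects")
  FeatureTable(.minmax(v), featureLabels(x), subjectIds(x),
               schema = descriptors(x), normalized = TRUE)
})

.minmax <- function(v) {
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1   # constant columns -> all zeros
  sweep(sweep(v, 2L, lo, "-"), 2L, span, "/")
}

#' Read a feature table from a delimited text file
#'
#' Expects a header row, one subject per row, a subject-id column (optional,
#' `subject_id`), a label column and numeric feature columns. Labels may be
#' coded `1`/`-1` or as the strings `ADHD`/`patient` (+1) and
#' `control`/`CS` (-1), case-insensitively. The field separator is sniffed
#' from the header (comma or tab).
#'
#' @param path file path.
#' @param labelColumn name of the label column (default `"diagnosis"`).
#' @return an un-normalized [FeatureTable-class]; the standard schema is
#'   attached when the feature headers match [standardSchema()] names,
#'   generic descriptors otherwise.
#' @export
readFeatureTable <- function(path, labelColumn = "diagnosis") {
  head1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", head1)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!(labelColumn %in% names(df)))
    stop("label column '", labelColumn, "' not found in ", path)
  idcol <- intersect(c("subject_id", "id"), names(df))[1]
  ids <- if (!is.na(idcol)) df[[idcol]] else sprintf("S%d", seq_len(nrow(df)))
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- .decodeLabels(df[[labelColumn]], labelColumn)
  featcols <- setdiff(names(df), c(labelColumn, if (!is.na(idcol)) idcol))
  vals <- matrix(NA_real_, nrow(df), length(featcols),
                 dimnames = list(NULL, featcols))
  for (j in seq_along(featcols)) {
    raw <- df[[featcols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num))
    if (length(bad))
      stop("non-numeric value '", raw[bad[1]], "' in column '",
           featcols[j], "', row ", bad[1])
    vals[, j] <- num
  }
  FeatureTable(vals, labels, ids, normalized = FALSE)
}

.decodeLabels <- function(raw, labelColumn) {
  low <- tolower(trimws(raw))
  out <- rep(NA_real_, length(raw))
  out[low %in% c("1", "+1", "adhd", "patient")] <- 1
  out[low %in% c("-1", "control", "cs", "healthy")] <- -1
  if (anyNA(out) && length(out))
    stop("label column '", labelColumn, "' contains uninterpretable value '",
         raw[which(is.na(out))[1]], "'")
  out
}

#' Write a feature table to a delimited text file
#'
#' Emits a header row (`subject_id`, `diagnosis`, then feature names), one
#' subject per row, labels as integers +1/-1, and feature values at full
#' precision (17 significant digits), so that
#' `readFeatureTable(writeFeatureTable(t))` reproduces values, labels and
#' ids exactly.
#'
#' @param table a [FeatureTable-class].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `invisible(path)`.
#' @export
writeFeatureTable <- function(table, path, sep = ",") {
  v <- featureValues(table)
  cols <- c("subject_id", "diagnosis", colnames(v))
  if (nrow(v) == 0L) {
    writeLines(paste(cols, collapse = sep), path)
    return(invisible(path))
  }
  txt <- apply(v, 2L, function(col) sprintf("%.17g", col))
  if (nrow(v) == 1L) txt <- matrix(txt, nrow = 1L)
  df <- cbind(data.frame(subject_id = subjectIds(table),
                         diagnosis = sprintf("%+d",
                           as.integer(featureLabels(table))),
                         stringsAsFactors = FALSE),
              as.data.frame(txt, stringsAsFactors = FALSE))
  names(df) <- cols
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a FeatureTable to a subset of features and/or subjects
#'
#' @param table a [FeatureTable-class].
#' @param features integer feature (column) indices to keep.
#' @param subjects integer subject (row) indices to keep.
#' @return a [FeatureTable-class].
#' @export
subsetFeatures <- function(table, features = NULL, subjects = NULL) {
  v <- featureValues(table)
  sch <- descriptors(table)
  lab <- featureLabels(table)
  ids <- subjectIds(table)
  if (!is.null(features)) {
    v <- v[, features, drop = FALSE]
    sch <- sch[features, , drop = FALSE]
  }
  if (!is.null(subjects)) {
    v <- v[subjects, , drop = FALSE]
    lab <- lab[subjects]
    ids <- ids[subjects]
  }
  FeatureTable(v, lab, ids, schema = sch, normalized = isNormalized(table))
}
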
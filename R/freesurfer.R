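## FreeSurfer per-hemisphere parcellation summary tables ("aparc stats"):
## '#'-prefixed metadata lines, a '# ColHeaders ...' line naming the data
## columns, then one whitespace-delimited row per parcel. The five schema
## measures map onto the standard columns:
.fsColumnFor <- c(thickness = "ThickAvg", surface_area = "SurfArea",
                  volume = "GrayVol", folding_index = "FoldInd",
                  curvature = "MeanCurv")

.readAparcStats <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  if (length(hdr) != 1L)
    stop("no '# ColHeaders' line found in ", path)
  cols <- strsplit(sub("^#\\s*ColHeaders\\s+", "", hdr), "\\s+")[[1]]
  data <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(data)) stop("no data rows in ", path)
  fields <- strsplit(trimws(data), "\\s+")
  if (any(lengths(fields) != length(cols)))
    stop("malformed data row in ", path,
         ": field count does not match ColHeaders")
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  as.data.frame(m, stringsAsFactors = FALSE)
}

#' Parse FreeSurfer per-hemisphere parcellation summaries into one
#' 340-feature record
#'
#' Reads the left- and right-hemisphere `aparc` summary tables produced by
#' cortical reconstruction and assembles the per-subject feature vector in
#' [standardSchema()] order. Region names are matched case-insensitively;
#' the measure columns used are `ThickAvg` (thickness), `SurfArea` (surface
#' area), `GrayVol` (volume), `FoldInd` (folding index) and `MeanCurv`
#' (curvature).
#'
#' @param lhPath,rhPath paths to the left/right hemisphere stats tables.
#' @param measures which measures to extract (default all five); the result
#'   still follows schema order, restricted to these measures.
#' @return named numeric vector, names being schema feature `name`s, in
#'   schema order (length 68 x number of measures).
#' @export
parseFreeSurferStats <- function(lhPath, rhPath,
                                 measures = corticalMeasures()) {
  measures <- match.arg(measures, corticalMeasures(), several.ok = TRUE)
  tabs <- list(left = .readAparcStats(lhPath), right = .readAparcStats(rhPath))
  need <- unname(.fsColumnFor[measures])
  for (h in names(tabs)) {
    if (!("StructName" %in% names(tabs[[h]])))
      stop("no 'StructName' column in the ", h, " hemisphere table")
    missingCols <- setdiff(need, names(tabs[[h]]))
    if (length(missingCols))
      stop("missing measure column(s) in the ", h, " hemisphere table: ",
           paste(missingCols, collapse = ", "))
  }
  sch <- standardSchema()
  sch <- sch[sch$measure %in% measures, , drop = FALSE]
  # check region coverage per hemisphere, reporting every absent parcel
  for (h in c("left", "right")) {
    have <- tolower(tabs[[h]]$StructName)
    want <- corticalRegions()
    absent <- setdiff(want, have)
    if (length(absent))
      stop("region(s) missing from the ", h, " hemisphere table: ",
           paste(absent, collapse = ", "))
  }
  out <- vapply(seq_len(nrow(sch)), function(i) {
    tab <- tabs[[sch$hemisphere[i]]]
    row <- match(sch$region[i], tolower(tab$StructName))
    val <- suppressWarnings(as.numeric(tab[[.fsColumnFor[sch$measure[i]]]][row]))
    if (is.na(val))
      stop("non-numeric ", sch$measure[i], " value for ", sch$hemisphere[i],
           " ", sch$region[i])
    val
  }, numeric(1))
  names(out) <- sch$name
  out
}

#' Assemble a FeatureTable from per-subject FreeSurfer stats files
#'
#' @param lhPaths,rhPaths character vectors of per-subject left/right
#'   hemisphere stats-table paths (parallel).
#' @param labels +1/-1 diagnosis labels, one per subject.
#' @param subjectIds optional subject identifiers.
#' @return an un-normalized [FeatureTable-class] with the standard 340-column
#'   schema.
#' @export
freeSurferCohort <- function(lhPaths, rhPaths, labels, subjectIds = NULL) {
  stopifnot(length(lhPaths) == length(rhPaths))
  rows <- t(vapply(seq_along(lhPaths),
                   function(i) parseFreeSurferStats(lhPaths[i], rhPaths[i]),
                   numeric(340L)))
  FeatureTable(rows, labels, subjectIds, schema = standardSchema(),
               normalized = FALSE)
}
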
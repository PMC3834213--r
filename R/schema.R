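## Cortical feature schema: 5 morphometric measures x 68 parcels = 340
## features. Indexing is 1-based and fixed:
##   1-68 thickness, 69-136 surface area, 137-204 volume,
##   205-272 folding index, 273-340 intrinsic curvature.
## Within each block the 68 parcels run left hemisphere first, then right,
## each hemisphere in the standard FreeSurfer Desikan-Killiany atlas order.

#' The 34 Desikan-Killiany cortical parcellation region names
#'
#' Lower-case, separator-free spellings, in the standard FreeSurfer
#' `aparc` table order. Each hemisphere contributes one parcel per name.
#'
#' @return character vector of length 34.
#' @export
corticalRegions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
}

#' The five morphometric measures, in schema block order
#'
#' @return character vector of length 5.
#' @export
corticalMeasures <- function() {
  c("thickness", "surface_area", "volume", "folding_index", "curvature")
}

#' The standard 340-feature cortical morphometry schema
#'
#' One descriptor per feature: `index` (1..340), `measure`, `hemisphere`
#' (`left`/`right`) and `region` (Desikan-Killiany parcel name). Index
#' blocks of 68 map to measures in the order thickness, surface area,
#' volume, folding index, curvature; within a block the parcel order is
#' the left hemisphere's 34 atlas regions followed by the right
#' hemisphere's, identically in all five blocks.
#'
#' @return a [S4Vectors::DataFrame] with 340 rows and columns
#'   `index`, `measure`, `hemisphere`, `region`, plus a `name` column
#'   (`<measure>_<lh|rh>_<region>`) used as the canonical column-header
#'   convention for on-disk feature tables.
#' @examples
#' sch <- standardSchema()
#' nrow(sch)              # 340
#' sch[271, ]             # folding_index, right, transversetemporal
#' @export
standardSchema <- function() {
  regions <- corticalRegions()
  measures <- corticalMeasures()
  hemi <- rep(c("left", "right"), each = 34L)
  reg <- rep(regions, 2L)
  n <- 5L * 68L
  DataFrame(
    index = seq_len(n),
    measure = rep(measures, each = 68L),
    hemisphere = rep(hemi, 5L),
    region = rep(reg, 5L),
    name = paste(rep(measures, each = 68L),
                 ifelse(rep(hemi, 5L) == "left", "lh", "rh"),
                 rep(reg, 5L), sep = "_")
  )
}

## Generic descriptors for tables whose columns are not the standard schema.
.genericSchema <- function(colnames) {
  n <- length(colnames)
  DataFrame(index = seq_len(n), measure = rep(NA_character_, n),
            hemisphere = rep(NA_character_, n),
            region = rep(NA_character_, n), name = colnames)
}

#' Short display label for features, Table-style: "[72, SA, L-Cuneus]"
#'
#' @param indices integer feature indices into the standard schema.
#' @param schema descriptor DataFrame, default [standardSchema()].
#' @return character vector of labels.
#' @export
featureLabel <- function(indices, schema = standardSchema()) {
  abbr <- c(thickness = "CT", surface_area = "SA", volume = "V",
            folding_index = "FI", curvature = "IC")
  stopifnot(all(indices >= 1L), all(indices <= nrow(schema)))
  m <- schema$measure[indices]
  h <- ifelse(schema$hemisphere[indices] == "left", "L", "R")
  r <- schema$region[indices]
  r <- paste0(toupper(substring(r, 1L, 1L)), substring(r, 2L))
  ifelse(is.na(m), sprintf("[%d]", indices),
         sprintf("[%d, %s, %s-%s]", indices, unname(abbr[m]), h, r))
}
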
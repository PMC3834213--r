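#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureValues", function(x, ...) standardGeneric("featureValues"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureLabels", function(x, ...) standardGeneric("featureLabels"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("descriptors", function(x, ...) standardGeneric("descriptors"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("isNormalized", function(x, ...) standardGeneric("isNormalized"))

#' @rdname normalizeMinMax
#' @export
setGeneric("normalizeMinMax", function(x, ...) standardGeneric("normalizeMinMax"))

#' @rdname FScoreRanking-accessors
#' @export
setGeneric("featureScores", function(x, ...) standardGeneric("featureScores"))

#' @rdname FScoreRanking-accessors
#' @export
setGeneric("featureOrder", function(x, ...) standardGeneric("featureOrder"))

#' @rdname rocCurve
#' @export
setGeneric("auc", function(x, ...) standardGeneric("auc"))

#' @rdname permutationTest
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname loocv
#' @export
setGeneric("testAccuracy", function(x, ...) standardGeneric("testAccuracy"))

#' @rdname sfs
#' @export
setGeneric("selectedFeatures", function(x, ...) standardGeneric("selectedFeatures"))
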
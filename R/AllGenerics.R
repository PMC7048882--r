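#' @rdname ItemParameters-class
#' @param object,x an object.
#' @export
setGeneric("itemId", function(x) standardGeneric("itemId"))

#' @rdname ItemParameters-class
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))

#' @rdname ItemParameters-class
#' @export
setGeneric("itemSlope", function(x) standardGeneric("itemSlope"))

#' @rdname ItemParameters-class
#' @export
setGeneric("itemThresholds", function(x) standardGeneric("itemThresholds"))

#' @rdname ItemParameters-class
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' @rdname ItemBank-class
#' @param x an \linkS4class{ItemBank}.
#' @export
setGeneric("bankId", function(x) standardGeneric("bankId"))

#' @rdname ItemBank-class
#' @export
setGeneric("bankItems", function(x) standardGeneric("bankItems"))

#' @rdname ItemBank-class
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname ItemBank-class
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))

#' @rdname ItemBank-class
#' @export
setGeneric("metricCenter", function(x) standardGeneric("metricCenter"))

#' @rdname ItemBank-class
#' @export
setGeneric("metricScale", function(x) standardGeneric("metricScale"))

#' @rdname TScoreMap-class
#' @param x a \linkS4class{TScoreMap}.
#' @export
setGeneric("mapBands", function(x) standardGeneric("mapBands"))

#' @rdname TScoreMap-class
#' @export
setGeneric("mapRange", function(x) standardGeneric("mapRange"))

#' @rdname TScoreMap-class
#' @export
setGeneric("omittedCategories", function(x) standardGeneric("omittedCategories"))

#' @rdname QuadratureGrid-class
#' @param x a \linkS4class{QuadratureGrid}.
#' @export
setGeneric("quadNodes", function(x) standardGeneric("quadNodes"))

#' @rdname QuadratureGrid-class
#' @export
setGeneric("quadWeights", function(x) standardGeneric("quadWeights"))

#' @rdname ScoreTable-class
#' @param x a \linkS4class{ScoreTable} or \linkS4class{ValidationReport}.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname ValidationReport-class
#' @param x a \linkS4class{ValidationReport}.
#' @export
setGeneric("reportItemStats", function(x) standardGeneric("reportItemStats"))

#' @rdname ValidationReport-class
#' @export
setGeneric("reportItemTables", function(x) standardGeneric("reportItemTables"))

#' @rdname ValidationReport-class
#' @export
setGeneric("reportScaleStats", function(x) standardGeneric("reportScaleStats"))

#' @rdname ValidationReport-class
#' @export
setGeneric("reportRecords", function(x) standardGeneric("reportRecords"))
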
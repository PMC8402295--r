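#' @rdname FSDataset-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FSDataset-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname FSDataset-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FSDataset-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname FSDataset-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname FSDataset-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname RankedList-accessors
#' @export
setGeneric("rankMethod", function(x) standardGeneric("rankMethod"))

#' @rdname RankedList-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname RankedList-accessors
#' @export
setGeneric("featureOrder", function(x) standardGeneric("featureOrder"))

#' @rdname StageResult-accessors
#' @export
setGeneric("orderedFeatures", function(x) standardGeneric("orderedFeatures"))

#' @rdname StageResult-accessors
#' @export
setGeneric("selectedSize", function(x) standardGeneric("selectedSize"))

#' @rdname StageResult-accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname StageResult-accessors
#' @export
setGeneric("accuracyTrace", function(x) standardGeneric("accuracyTrace"))

#' @rdname PruneResult-accessors
#' @export
setGeneric("keptFeatures", function(x) standardGeneric("keptFeatures"))

#' @rdname PruneResult-accessors
#' @export
setGeneric("discardAudit", function(x) standardGeneric("discardAudit"))
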
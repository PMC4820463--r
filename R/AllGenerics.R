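#' @rdname VoxelGrid-class
#' @param object,x an object.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname VoxelGrid-class
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))
#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname ROIDefinition-class
#' @export
setGeneric("roiName", function(x) standardGeneric("roiName"))
#' @rdname ROIDefinition-class
#' @export
setGeneric("roiVoxels", function(x) standardGeneric("roiVoxels"))
#' @rdname ROIDefinition-class
#' @export
setGeneric("roiSize", function(x) standardGeneric("roiSize"))
#' @rdname ROIDefinition-class
#' @export
setGeneric("roiGrid", function(x) standardGeneric("roiGrid"))

#' @rdname SessionTimeSeries-class
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname SessionTimeSeries-class
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))

#' @rdname BinaryConnectivityMatrix-class
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))
#' @rdname BinaryConnectivityMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SubRegionalPair-class
#' @export
setGeneric("membersA", function(x) standardGeneric("membersA"))
#' @rdname SubRegionalPair-class
#' @export
setGeneric("membersB", function(x) standardGeneric("membersB"))
#' @rdname SubRegionalPair-class
#' @export
setGeneric("fitnessOf", function(x) standardGeneric("fitnessOf"))

#' @rdname ECResult-class
#' @export
setGeneric("srps", function(x) standardGeneric("srps"))
#' @rdname ECResult-class
#' @export
setGeneric("detectedPairs", function(x) standardGeneric("detectedPairs"))

#' @rdname PlasticityEstimate-class
#' @export
setGeneric("pctPositive", function(x) standardGeneric("pctPositive"))
#' @rdname PlasticityEstimate-class
#' @export
setGeneric("pctNegative", function(x) standardGeneric("pctNegative"))
#' @rdname PlasticityEstimate-class
#' @export
setGeneric("gl1", function(x) standardGeneric("gl1"))
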
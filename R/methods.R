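#' @rdname VoxelGrid-class
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
#' @rdname VoxelGrid-class
setMethod("gridAffine", "VoxelGrid", function(x) x@affine)
#' @rdname VoxelGrid-class
setMethod("voxelSize", "VoxelGrid", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' @rdname ROIDefinition-class
setMethod("roiName", "ROIDefinition", function(x) x@name)
#' @rdname ROIDefinition-class
setMethod("roiVoxels", "ROIDefinition", function(x) x@voxels)
#' @rdname ROIDefinition-class
setMethod("roiSize", "ROIDefinition", function(x) nrow(x@voxels))
#' @rdname ROIDefinition-class
setMethod("roiGrid", "ROIDefinition", function(x) x@grid)

#' @rdname SessionTimeSeries-class
setMethod("sessionId", "SessionTimeSeries", function(x) x@session)
#' @rdname SessionTimeSeries-class
setMethod("tsData", "SessionTimeSeries", function(x) x@data)

#' @rdname BinaryConnectivityMatrix-class
setMethod("connMatrix", "BinaryConnectivityMatrix", function(x) x@M)
#' @rdname BinaryConnectivityMatrix-class
setMethod("nSamples", "BinaryConnectivityMatrix", function(x) x@nSamples)
#' @rdname BinaryConnectivityMatrix-class
setMethod("sessionId", "BinaryConnectivityMatrix", function(x) x@session)

#' @rdname SubRegionalPair-class
setMethod("membersA", "SubRegionalPair", function(x) x@membersA)
#' @rdname SubRegionalPair-class
setMethod("membersB", "SubRegionalPair", function(x) x@membersB)
#' @rdname SubRegionalPair-class
setMethod("fitnessOf", "SubRegionalPair", function(x) x@fitness)

#' @rdname ECResult-class
setMethod("srps", "ECResult", function(x) x@srps)
#' @rdname ECResult-class
setMethod("detectedPairs", "ECResult", function(x) x@detected)

#' @rdname PlasticityEstimate-class
setMethod("pctPositive", "PlasticityEstimate", function(x) x@pctPositive)
#' @rdname PlasticityEstimate-class
setMethod("pctNegative", "PlasticityEstimate", function(x) x@pctNegative)
#' @rdname PlasticityEstimate-class
setMethod("gl1", "PlasticityEstimate", function(x) x@gl1)

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@shape, collapse = " x "),
      "voxels,", paste(signif(voxelSize(object), 4), collapse = " x "),
      "mm\n")
})

setMethod("show", "ROIDefinition", function(object) {
  cat("ROIDefinition '", object@name, "': ", nrow(object@voxels),
      " voxels on a ", paste(object@grid@shape, collapse = "x"),
      " grid\n", sep = "")
})

setMethod("show", "SessionTimeSeries", function(object) {
  cat("SessionTimeSeries (session ", object@session, "): ",
      nrow(object@data), " voxels x ", ncol(object@data),
      " time points\n", sep = "")
})

setMethod("show", "BinaryConnectivityMatrix", function(object) {
  cat("BinaryConnectivityMatrix (session ", object@session, "): ",
      nrow(object@M), " x ", ncol(object@M), ", ",
      sum(object@M), " edges", sep = "")
  if (object@nSamples > 0) cat(", T =", object@nSamples)
  cat("\n")
})

setMethod("show", "ECConfig", function(object) {
  cat("ECConfig: population ", object@populationSize,
      ", offsets ", paste(unique(object@offsetMm), collapse = "/"),
      " mm, dl ", paste(unique(object@dl), collapse = "/"),
      ", stall ", object@stallGenerations,
      ", zStop ", object@zStop, ", alpha ", object@alpha,
      ", L lattice {", object@lMin, ", +", object@lStep,
      ", ...}, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "SubRegionalPair", function(object) {
  cat("SubRegionalPair (level ", object@level, "): |A| = ",
      length(object@membersA), ", |B| = ", length(object@membersB),
      ", NC1 = ", object@NC1, ", NC2 = ", object@NC2,
      ", Z = ", signif(object@Z, 5), sep = "")
  if (!is.na(object@pCorrected))
    cat(", corrected p = ", signif(object@pCorrected, 3), sep = "")
  cat("\n")
})

setMethod("show", "ECResult", function(object) {
  cat("ECResult: ", length(object@srps), " surviving of ",
      length(object@detected), " detected sub-regional pair(s) over ",
      length(object@generationsRun), " recursion level(s); seed ",
      object@seed, "\n", sep = "")
})

setMethod("show", "PlasticityEstimate", function(object) {
  cat("PlasticityEstimate: +", signif(object@pctPositive, 5), "% / -",
      signif(object@pctNegative, 5), "% of ", object@totalPossible,
      " possible edges (gl1 = ", object@gl1, ")\n", sep = "")
})
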
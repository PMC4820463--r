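#' @import methods
NULL

#' Voxel grid geometry
#'
#' A \code{VoxelGrid} describes the common 3-D sampling grid on which both
#' BOLD sessions and the ROI label volume live: integer dimensions plus a
#' 4x4 affine mapping 0-based voxel indices (i,j,k) to scanner/world mm
#' coordinates, as in the NIfTI-1 convention.
#'
#' @slot shape integer vector of length 3, grid dimensions.
#' @slot affine 4x4 numeric matrix, invertible; maps homogeneous 0-based
#'   voxel indices to mm.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be 3 positive integers")
    if (!identical(dim(object@affine), c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else if (abs(det(object@affine)) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    if (length(msg)) msg else TRUE
  })

#' Construct a VoxelGrid
#'
#' @param shape grid dimensions (3 positive integers).
#' @param affine 4x4 voxel-to-mm affine; if \code{NULL}, a diagonal affine
#'   built from \code{voxelSize} is used.
#' @param voxelSize voxel edge lengths in mm (default 3 mm isotropic, the
#'   common resliced resolution for normalized BOLD data).
#' @return A \code{VoxelGrid}.
#' @examples
#' g <- VoxelGrid(c(10, 10, 10))
#' voxelSize(g)
#' @export
VoxelGrid <- function(shape, affine = NULL, voxelSize = c(3, 3, 3)) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("VoxelGrid", shape = as.integer(shape), affine = affine)
}

#' Region-of-interest definition
#'
#' An ordered list of distinct 0-based voxel coordinates on a
#' \code{VoxelGrid}. Row order is the identity used for the rows/columns of
#' all connectivity matrices, so it must be held fixed across the pipeline.
#'
#' @slot name character ROI name.
#' @slot voxels n x 3 integer matrix of 0-based (i,j,k) coordinates.
#' @slot grid the \code{VoxelGrid} the coordinates refer to.
#' @export
setClass("ROIDefinition",
  representation(name = "character", voxels = "matrix", grid = "VoxelGrid"),
  validity = function(object) {
    v <- object@voxels
    msg <- character(0)
    if (!is.numeric(v) || ncol(v) != 3L || nrow(v) < 1L)
      msg <- c(msg, "voxels must be a non-empty n x 3 matrix")
    else {
      if (anyDuplicated(paste(v[, 1], v[, 2], v[, 3])))
        msg <- c(msg, "voxels must be distinct")
      sh <- object@grid@shape
      if (any(v < 0) || any(v[, 1] >= sh[1] | v[, 2] >= sh[2] | v[, 3] >= sh[3]))
        msg <- c(msg, "voxels must lie within grid bounds (0-based)")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a ROIDefinition
#'
#' @param name ROI name.
#' @param voxels n x 3 matrix of 0-based voxel coordinates.
#' @param grid a \code{VoxelGrid}.
#' @return A \code{ROIDefinition}.
#' @export
ROIDefinition <- function(name, voxels, grid) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  colnames(voxels) <- c("i", "j", "k")
  new("ROIDefinition", name = as.character(name), voxels = voxels, grid = grid)
}

#' Per-session ROI time series
#'
#' BOLD samples for one ROI in one session: a voxels x T matrix whose row
#' order matches the owning \code{ROIDefinition}.
#'
#' @slot session integer session id (1 or 2).
#' @slot data numeric matrix, |ROI voxels| x T.
#' @export
setClass("SessionTimeSeries",
  representation(session = "integer", data = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (!object@session %in% c(1L, 2L))
      msg <- c(msg, "session must be 1 or 2")
    if (ncol(object@data) < 3L)
      msg <- c(msg, "need at least 3 time points for a Pearson p-value")
    if (length(msg)) msg else TRUE
  })

#' Construct a SessionTimeSeries
#'
#' @param session session id, 1 or 2.
#' @param data voxels x T numeric matrix.
#' @return A \code{SessionTimeSeries}.
#' @export
SessionTimeSeries <- function(session, data) {
  new("SessionTimeSeries", session = as.integer(session),
      data = as.matrix(data))
}

#' Binary voxel-level connectivity matrix
#'
#' The per-session |A| x |B| 0/1 matrix of FDR-surviving positive Pearson
#' edges between a ROI pair (M1 for session 1, M2 for session 2).
#'
#' @slot session integer session id.
#' @slot M |A| x |B| matrix with entries in {0,1}.
#' @slot nSamples number of time points the p-values used (0 when the
#'   matrix was constructed directly, e.g. by the synthetic generator).
#' @export
setClass("BinaryConnectivityMatrix",
  representation(session = "integer", M = "matrix", nSamples = "integer"),
  validity = function(object) {
    if (!all(object@M %in% c(0, 1)))
      "entries of M must be exactly 0 or 1"
    else TRUE
  })

#' Construct a BinaryConnectivityMatrix
#'
#' @param session session id, 1 or 2.
#' @param M 0/1 matrix.
#' @param nSamples time points behind the p-values (0 if not applicable).
#' @return A \code{BinaryConnectivityMatrix}.
#' @export
BinaryConnectivityMatrix <- function(session, M, nSamples = 0L) {
  storage.mode(M) <- "double"
  new("BinaryConnectivityMatrix", session = as.integer(session), M = M,
      nSamples = as.integer(nSamples))
}

#' Evolutionary search configuration
#'
#' Holds every tunable of the evolutionary search. Defaults are the
#' published operating point for whole-ROI analyses at 3 mm resolution:
#' population 400, 6 mm spatial mutation offsets, size-gene offsets of 4
#' lattice steps, 100-generation stall criterion, z-score stop threshold 1,
#' Bonferroni alpha 0.05, and a size-gene lattice starting at 64 voxels
#' with step 5. Tiny synthetic ROIs typically use \code{lMin = 1},
#' \code{lStep = 1} and a smaller population.
#'
#' @slot populationSize even integer >= 2.
#' @slot offsetMm numeric length 6: mutation half-ranges (dx1,dy1,dz1,
#'   dx2,dy2,dz2) in mm.
#' @slot dl numeric length 2: size-gene mutation half-ranges, in lattice
#'   steps.
#' @slot offspringPerParent integer >= 1.
#' @slot stallGenerations stop a level after this many generations without
#'   best-ever improvement.
#' @slot zStop stop recursing when the best |Z| falls below this.
#' @slot alpha Bonferroni-corrected significance level.
#' @slot maxRecursion cap on recursion levels (Inf = unbounded).
#' @slot lMin,lStep size-gene quantization lattice {lMin, lMin+lStep, ...},
#'   capped at the ROI size.
#' @slot seed RNG seed used by \code{detectAllSRPs}.
#' @export
setClass("ECConfig",
  representation(populationSize = "integer", offsetMm = "numeric",
                 dl = "numeric", offspringPerParent = "integer",
                 stallGenerations = "integer", zStop = "numeric",
                 alpha = "numeric", maxRecursion = "numeric",
                 lMin = "integer", lStep = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@populationSize < 2L || object@populationSize %% 2L != 0L)
      msg <- c(msg, "populationSize must be even and >= 2")
    if (length(object@offsetMm) != 6L || any(object@offsetMm < 0))
      msg <- c(msg, "offsetMm must be 6 non-negative values")
    if (length(object@dl) != 2L || any(object@dl < 0))
      msg <- c(msg, "dl must be 2 non-negative values")
    if (object@offspringPerParent < 1L)
      msg <- c(msg, "offspringPerParent must be >= 1")
    if (object@lMin < 1L || object@lStep < 1L)
      msg <- c(msg, "lMin and lStep must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Construct an ECConfig
#'
#' @param populationSize population size (default 400).
#' @param offsetMm spatial mutation half-range(s) in mm; recycled to 6
#'   values (default 6 mm).
#' @param dl size-gene mutation half-range(s) in lattice steps; recycled to
#'   2 values (default 4).
#' @param offspringPerParent offspring per parent per generation (default 1,
#'   so elitist selection keeps the top 50\% of the pooled set).
#' @param stallGenerations stall criterion (default 100).
#' @param zStop recursion stop threshold on |Z| (default 1).
#' @param alpha corrected significance level (default 0.05).
#' @param maxRecursion recursion cap (default Inf).
#' @param lMin,lStep size-gene lattice origin and step (defaults 64 and 5).
#' @param seed RNG seed (default 1).
#' @return An \code{ECConfig}.
#' @examples
#' cfg <- ECConfig(populationSize = 40, lMin = 1, lStep = 1, seed = 7)
#' @export
ECConfig <- function(populationSize = 400L, offsetMm = 6, dl = 4,
                     offspringPerParent = 1L, stallGenerations = 100L,
                     zStop = 1, alpha = 0.05, maxRecursion = Inf,
                     lMin = 64L, lStep = 5L, seed = 1L) {
  new("ECConfig",
      populationSize = as.integer(populationSize),
      offsetMm = rep_len(as.numeric(offsetMm), 6L),
      dl = rep_len(as.numeric(dl), 2L),
      offspringPerParent = as.integer(offspringPerParent),
      stallGenerations = as.integer(stallGenerations),
      zStop = as.numeric(zStop), alpha = as.numeric(alpha),
      maxRecursion = as.numeric(maxRecursion),
      lMin = as.integer(lMin), lStep = as.integer(lStep),
      seed = as.integer(seed))
}

#' A sub-regional pair with its fitness bookkeeping
#'
#' One spatially 6-connected sub-region from each ROI of a pair, plus the
#' binomial-test statistics of its between-session edge-count change.
#' Member indices are 1-based rows of the owning \code{ROIDefinition}s.
#'
#' @slot level recursion level at which the pair was detected (0 if not
#'   produced by the recursive search).
#' @slot rootA,rootB 1-based ROI index of each root voxel.
#' @slot membersA,membersB sorted 1-based ROI member indices (roots
#'   included).
#' @slot NC1,NC2 edge counts in M1 and M2 over the member submatrix.
#' @slot TC total possible connections, |membersA| * |membersB|.
#' @slot EC2 expected session-2 edge count under the session-1 rate.
#' @slot SD binomial standard deviation.
#' @slot Z signed z-score (NC2 - EC2)/SD.
#' @slot sign +1, -1 or 0 = sign(NC2 - NC1).
#' @slot fitness |Z|.
#' @slot pRaw,pCorrected two-sided normal tail p-value and its Bonferroni
#'   correction (NA until \code{bonferroniFilter} runs).
#' @export
setClass("SubRegionalPair",
  representation(level = "integer", rootA = "integer", rootB = "integer",
                 membersA = "integer", membersB = "integer",
                 NC1 = "numeric", NC2 = "numeric", TC = "numeric",
                 EC2 = "numeric", SD = "numeric", Z = "numeric",
                 sign = "integer", fitness = "numeric",
                 pRaw = "numeric", pCorrected = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@membersA) < 1L || length(object@membersB) < 1L)
      msg <- c(msg, "sub-regions must be non-empty")
    if (length(object@TC) == 1L &&
        object@TC != length(object@membersA) * length(object@membersB))
      msg <- c(msg, "TC must equal |membersA| * |membersB|")
    if (length(object@NC1) == 1L && length(object@NC2) == 1L &&
        !anyNA(c(object@NC1, object@NC2)) &&
        (object@NC1 < 0 || object@NC2 < 0 ||
         object@NC1 > object@TC || object@NC2 > object@TC))
      msg <- c(msg, "NC1 and NC2 must lie in [0, TC]")
    if (length(msg)) msg else TRUE
  })

#' Ordered result of the recursive evolutionary search
#'
#' @slot srps list of Bonferroni-surviving \code{SubRegionalPair}s in
#'   detection order.
#' @slot detected every pair recorded before correction, in detection
#'   order (corrected p-values filled in).
#' @slot generationsRun integer vector, generations run per recursion
#'   level.
#' @slot bestFitnessTrace list of per-level best-ever fitness traces.
#' @slot seed RNG seed used.
#' @slot config the \code{ECConfig} used.
#' @slot dims integer c(|A|, |B|).
#' @export
setClass("ECResult",
  representation(srps = "list", detected = "list",
                 generationsRun = "integer", bestFitnessTrace = "list",
                 seed = "integer", config = "ECConfig", dims = "integer"),
  validity = function(object) {
    ok <- vapply(object@srps, function(s)
      is(s, "SubRegionalPair") && !is.na(s@pCorrected), logical(1))
    if (!all(ok)) return("srps must be corrected SubRegionalPair objects")
    TRUE
  })

#' Subject-level plasticity estimate
#'
#' Percent of the total possible voxel-wise connections between a ROI pair
#' that contribute to positive (edge-gaining) and negative (edge-losing)
#' plasticity across the surviving sub-regional pairs, plus the overall
#' gained+lost edge count gl1.
#'
#' @slot pctPositive,pctNegative percentages of |A| x |B|.
#' @slot gl1 edges gained plus edges lost over surviving pairs.
#' @slot totalPossible |A| x |B|.
#' @export
setClass("PlasticityEstimate",
  representation(pctPositive = "numeric", pctNegative = "numeric",
                 gl1 = "numeric", totalPossible = "numeric"),
  validity = function(object) {
    if (object@pctPositive < 0 || object@pctNegative < 0)
      return("percentages must be non-negative")
    if (object@pctPositive + object@pctNegative > 100 + 1e-9)
      return("pctPositive + pctNegative cannot exceed 100")
    TRUE
  })
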
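# The chromosome is an 8-vector:
#   (x1, y1, z1, li1, x2, y2, z2, li2)
# where x/y/z are mm coordinates inside the ROI's bounding cuboid (over
# voxel centers, boundary inclusive) and li is a 0-based index into the
# size-gene lattice {lMin, lMin + lStep, ...} capped at the ROI size.
# Decoding factors through (root voxel, L): the nearest ROI voxel center
# to the point is the root, and L voxels are added by deterministic BFS.

# Precomputed per-ROI search context.
.roiContext <- function(roi, lMin, lStep) {
  centers <- voxelCenters(roiGrid(roi), roiVoxels(roi))
  n <- roiSize(roi)
  lVals <- seq.int(min(lMin, n), n, by = lStep)
  list(roi = roi, n = n, centers = centers,
       lo = apply(centers, 2, min), hi = apply(centers, 2, max),
       nbrs = .neighborList(roi), lVals = lVals, nL = length(lVals))
}

# Nearest ROI voxel to a mm point; ties (within 1e-9 of the minimal
# distance) broken by smallest z, then y, then x center coordinate.
.decodeRootCtx <- function(pointMm, ctx) {
  d2 <- (ctx$centers[, 1] - pointMm[1])^2 +
        (ctx$centers[, 2] - pointMm[2])^2 +
        (ctx$centers[, 3] - pointMm[3])^2
  cand <- which(d2 <= min(d2) + 1e-9)
  if (length(cand) > 1L)
    cand <- cand[order(ctx$centers[cand, 3], ctx$centers[cand, 2],
                       ctx$centers[cand, 1])]
  cand[1]
}

# FIFO BFS from root over 6-adjacency restricted to the ROI; at each
# dequeue the unvisited neighbours are enqueued sorted ascending by
# (z, y, x) center coordinate. Members = root + first L enqueued voxels,
# capped at the root's connected component.
.growBFSCtx <- function(root, ctx, L) {
  if (L <= 0) return(root)
  visited <- logical(ctx$n)
  visited[root] <- TRUE
  queue <- integer(ctx$n)
  queue[1] <- root
  head <- 1L; tail <- 1L
  enq <- 0L
  while (head <= tail && enq < L) {
    v <- queue[head]; head <- head + 1L
    nb <- ctx$nbrs[[v]]
    nb <- nb[!visited[nb]]
    if (length(nb) > 1L)
      nb <- nb[order(ctx$centers[nb, 3], ctx$centers[nb, 2],
                     ctx$centers[nb, 1])]
    if (length(nb)) {
      visited[nb] <- TRUE
      queue[(tail + 1L):(tail + length(nb))] <- nb
      tail <- tail + length(nb)
      enq <- enq + length(nb)
    }
  }
  keep <- min(1L + L, tail)
  sort(queue[seq_len(keep)])
}

#' Decode a root voxel from a mm point
#'
#' Returns the 1-based ROI index of the voxel whose center is closest (in
#' Euclidean mm distance) to the given point; ties are broken by the
#' smallest z, then y, then x center coordinate.
#'
#' @param pointMm numeric length-3 mm coordinate.
#' @param roi a \code{ROIDefinition}.
#' @return integer ROI voxel index.
#' @export
decodeRootVoxel <- function(pointMm, roi) {
  if (roiSize(roi) < 1L) stop("empty ROI")
  ctx <- list(centers = voxelCenters(roiGrid(roi), roiVoxels(roi)))
  .decodeRootCtx(pointMm, ctx)
}

#' Grow a sub-region by breadth-first search
#'
#' Deterministic FIFO BFS from the root over 6-neighbor adjacency
#' restricted to ROI voxels; at every frontier expansion the unvisited
#' neighbors are enqueued in ascending (z, y, x) order. The sub-region is
#' the root plus the first \code{L} voxels enqueued; if fewer than
#' \code{L} voxels are reachable the root's whole connected component is
#' returned.
#'
#' @param root 1-based ROI index of the root voxel.
#' @param roi a \code{ROIDefinition}.
#' @param L number of voxels to add beyond the root (>= 0).
#' @return sorted integer vector of member indices (root included).
#' @export
growSubregionBFS <- function(root, roi, L) {
  if (root < 1L || root > roiSize(roi)) stop("root is not a ROI voxel")
  if (L < 0) stop("L must be >= 0")
  ctx <- list(n = roiSize(roi),
              centers = voxelCenters(roiGrid(roi), roiVoxels(roi)),
              nbrs = .neighborList(roi))
  .growBFSCtx(as.integer(root), ctx, as.integer(L))
}

#' Decode a chromosome into a sub-regional pair (geometry only)
#'
#' @param chrom numeric length-8 chromosome (x1, y1, z1, li1, x2, y2, z2,
#'   li2); the li genes are 0-based indices into the size lattice.
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @param lMin,lStep size-gene lattice origin and step.
#' @return A \code{SubRegionalPair} with geometry set and counts NA.
#' @export
decodeChromosome <- function(chrom, roiA, roiB, lMin = 1L, lStep = 1L) {
  ctxA <- .roiContext(roiA, lMin, lStep)
  ctxB <- .roiContext(roiB, lMin, lStep)
  rootA <- .decodeRootCtx(chrom[1:3], ctxA)
  rootB <- .decodeRootCtx(chrom[5:7], ctxB)
  mA <- .growBFSCtx(rootA, ctxA, ctxA$lVals[chrom[4] + 1])
  mB <- .growBFSCtx(rootB, ctxB, ctxB$lVals[chrom[8] + 1])
  .newSRP(rootA, rootB, mA, mB)
}

# SubRegionalPair with counts unset.
.newSRP <- function(rootA, rootB, mA, mB, level = 0L) {
  new("SubRegionalPair", level = as.integer(level),
      rootA = as.integer(rootA), rootB = as.integer(rootB),
      membersA = as.integer(mA), membersB = as.integer(mB),
      NC1 = NA_real_, NC2 = NA_real_,
      TC = as.numeric(length(mA)) * length(mB),
      EC2 = NA_real_, SD = NA_real_, Z = NA_real_, sign = 0L,
      fitness = NA_real_, pRaw = NA_real_, pCorrected = NA_real_)
}

# Random chromosome: points uniform over the bounding cuboid, lattice
# index uniform over the lattice.
.randomChromosome <- function(ctxA, ctxB) {
  c(stats::runif(3, ctxA$lo, ctxA$hi),
    sample.int(ctxA$nL, 1L) - 1L,
    stats::runif(3, ctxB$lo, ctxB$hi),
    sample.int(ctxB$nL, 1L) - 1L)
}
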
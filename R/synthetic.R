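#' Generate two disjoint 6-connected ROIs on a 3-D grid
#'
#' Each ROI is grown by randomized breadth-first accretion from a random
#' seed voxel: at every step a uniformly chosen frontier voxel (a grid
#' neighbor of the current set, outside the other ROI) is added until the
#' requested size is reached. Growth retries from a new seed when it gets
#' stuck.
#'
#' @param shape grid dimensions (default 12 x 12 x 12).
#' @param roiSizes integer vector of 2 ROI sizes in voxels.
#' @param voxelSize voxel edge lengths in mm (default 3 mm isotropic).
#' @param maxTries seed retries before giving up.
#' @return list with \code{grid}, \code{roiA}, \code{roiB}.
#' @examples
#' set.seed(1)
#' geo <- makeGeometry(c(6, 6, 6), c(8, 6))
#' @export
makeGeometry <- function(shape = c(12, 12, 12), roiSizes = c(60, 60),
                         voxelSize = c(3, 3, 3), maxTries = 100L) {
  if (sum(roiSizes) > prod(shape))
    stop("ROI sizes do not fit in the grid")
  grid <- VoxelGrid(shape, voxelSize = voxelSize)
  voxA <- .growRandomROI(shape, roiSizes[1], forbidden = NULL, maxTries)
  voxB <- .growRandomROI(shape, roiSizes[2], forbidden = voxA, maxTries)
  list(grid = grid,
       roiA = ROIDefinition("roiA", voxA, grid),
       roiB = ROIDefinition("roiB", voxB, grid))
}

.growRandomROI <- function(shape, size, forbidden, maxTries) {
  forbid <- if (is.null(forbidden)) integer(0)
            else .linearIndex(forbidden, shape)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (try in seq_len(maxTries)) {
    seedVox <- c(sample.int(shape[1], 1), sample.int(shape[2], 1),
                 sample.int(shape[3], 1)) - 1L
    if (.linearIndex(matrix(seedVox, 1), shape) %in% forbid) next
    members <- matrix(seedVox, 1)
    memberKeys <- .linearIndex(members, shape)
    while (nrow(members) < size) {
      cand <- do.call(rbind, lapply(seq_len(nrow(members)), function(v)
        sweep(offs, 2, members[v, ], "+")))
      ok <- cand[, 1] >= 0 & cand[, 2] >= 0 & cand[, 3] >= 0 &
        cand[, 1] < shape[1] & cand[, 2] < shape[2] & cand[, 3] < shape[3]
      cand <- cand[ok, , drop = FALSE]
      keys <- .linearIndex(cand, shape)
      new <- !(keys %in% c(memberKeys, forbid))
      if (!any(new)) break
      pick <- which(new)[sample.int(sum(new), 1)]
      members <- rbind(members, cand[pick, ])
      memberKeys <- c(memberKeys, keys[pick])
    }
    if (nrow(members) == size) return(unname(members))
  }
  stop("could not grow a connected ROI of size ", size,
       " after ", maxTries, " tries")
}

#' Planted ground truth for the generators
#'
#' Describes the plastic structure a synthetic dataset carries: a
#' background edge density (or noise-only background for the time-series
#' generator) and a list of planted blocks, each a 6-connected sub-region
#' in each ROI with session-specific edge densities (matrix generator) or
#' latent-signal coupling amplitudes (time-series generator).
#'
#' @param blocks list of blocks; each is a list with \code{membersA},
#'   \code{membersB} (1-based ROI indices) and either \code{d1},
#'   \code{d2} (densities in [0, 1]) or \code{c1}, \code{c2} (coupling
#'   amplitudes >= 0).
#' @param background background edge density (matrix generator) in
#'   [0, 1]; ignored by the time-series generator.
#' @return list of class \code{"PlantedTruth"}.
#' @export
plantedTruth <- function(blocks, background = 0) {
  for (b in blocks) {
    stopifnot(length(b$membersA) >= 1L, length(b$membersB) >= 1L)
  }
  structure(list(blocks = blocks, background = background),
            class = "PlantedTruth")
}

#' Plant a random 6-connected block pair
#'
#' Convenience helper: picks a random root in each ROI and grows the
#' requested sizes by the same deterministic BFS the decoder uses, so the
#' planted sub-regions are valid decodable shapes.
#'
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @param sizeA,sizeB block sizes in voxels.
#' @param ... session parameters stored on the block (\code{d1},
#'   \code{d2} or \code{c1}, \code{c2}).
#' @return a block list for \code{plantedTruth}.
#' @export
plantBlock <- function(roiA, roiB, sizeA, sizeB, ...) {
  rootA <- sample.int(roiSize(roiA), 1)
  rootB <- sample.int(roiSize(roiB), 1)
  c(list(membersA = growSubregionBFS(rootA, roiA, sizeA - 1L),
         membersB = growSubregionBFS(rootB, roiB, sizeB - 1L)), ...)
}

#' Generate a pair of binary matrices with planted plasticity
#'
#' Produces (M1, M2) directly, bypassing the correlation/FDR stage, for
#' testing the search in isolation. Every cell has a session-1 and a
#' session-2 Bernoulli density (background outside the planted blocks).
#' Cells whose two densities are equal are drawn once and shared between
#' the sessions -- unchanged functional structure is stable across
#' sessions -- while cells with differing densities are drawn
#' independently per session.
#'
#' @param truth a \code{plantedTruth} with \code{d1}/\code{d2} blocks.
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @return list with \code{M1}, \code{M2}
#'   (\code{BinaryConnectivityMatrix}) and \code{truth}.
#' @export
makeMatrixDataset <- function(truth, roiA, roiB) {
  nA <- roiSize(roiA); nB <- roiSize(roiB)
  D1 <- matrix(truth$background, nA, nB)
  D2 <- D1
  support <- matrix(FALSE, nA, nB)
  for (b in truth$blocks) {
    if (any(support[b$membersA, b$membersB]))
      stop("planted blocks must have disjoint edge supports")
    support[b$membersA, b$membersB] <- TRUE
    D1[b$membersA, b$membersB] <- b$d1
    D2[b$membersA, b$membersB] <- b$d2
  }
  U <- matrix(stats::runif(nA * nB), nA, nB)
  M1 <- (U < D1) + 0
  M2 <- (U < D2) + 0
  changed <- D1 != D2
  if (any(changed)) {
    U2 <- matrix(stats::runif(nA * nB), nA, nB)
    M2[changed] <- (U2[changed] < D2[changed]) + 0
  }
  list(M1 = BinaryConnectivityMatrix(1L, M1),
       M2 = BinaryConnectivityMatrix(2L, M2), truth = truth)
}

#' Generate two-session voxel time series with planted coupling
#'
#' Each planted block has one latent standard-normal signal per session,
#' added to all member voxels of both ROIs with the block's
#' session-specific coupling amplitude; every voxel additionally carries
#' i.i.d. Gaussian noise of unit variance. A higher session-2 coupling
#' therefore induces a block of stronger positive voxel-wise correlations
#' in session 2, i.e. positive plasticity through the full
#' correlation/FDR pipeline.
#'
#' @param truth a \code{plantedTruth} with \code{c1}/\code{c2} blocks.
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @param T number of time points per session (default 145).
#' @return list with \code{tsA1}, \code{tsA2}, \code{tsB1}, \code{tsB2}
#'   (\code{SessionTimeSeries}) and \code{truth}.
#' @export
makeTimeseriesDataset <- function(truth, roiA, roiB, T = 145L) {
  nA <- roiSize(roiA); nB <- roiSize(roiB)
  mk <- function(n) matrix(stats::rnorm(n * T), n, T)
  out <- list(tsA1 = mk(nA), tsA2 = mk(nA), tsB1 = mk(nB), tsB2 = mk(nB))
  for (b in truth$blocks) {
    for (s in 1:2) {
      coup <- if (s == 1) b$c1 else b$c2
      latent <- stats::rnorm(T)
      kA <- paste0("tsA", s); kB <- paste0("tsB", s)
      out[[kA]][b$membersA, ] <- out[[kA]][b$membersA, , drop = FALSE] +
        coup * matrix(latent, length(b$membersA), T, byrow = TRUE)
      out[[kB]][b$membersB, ] <- out[[kB]][b$membersB, , drop = FALSE] +
        coup * matrix(latent, length(b$membersB), T, byrow = TRUE)
    }
  }
  list(tsA1 = SessionTimeSeries(1L, out$tsA1),
       tsA2 = SessionTimeSeries(2L, out$tsA2),
       tsB1 = SessionTimeSeries(1L, out$tsB1),
       tsB2 = SessionTimeSeries(2L, out$tsB2),
       truth = truth)
}
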
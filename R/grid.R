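#' Voxel centers in mm
#'
#' Maps 0-based voxel indices through a grid's affine to mm coordinates of
#' the voxel centers.
#'
#' @param grid a \code{VoxelGrid}.
#' @param voxels n x 3 matrix of 0-based (i,j,k) indices.
#' @return n x 3 numeric matrix of mm coordinates.
#' @export
voxelCenters <- function(grid, voxels) {
  voxels <- matrix(voxels, ncol = 3)
  hom <- cbind(voxels, 1)
  out <- hom %*% t(gridAffine(grid))
  out[, 1:3, drop = FALSE]
}

# Linear (column-major, i fastest) 0-based voxel key for hashing/ordering.
.linearIndex <- function(voxels, shape) {
  voxels[, 1] + shape[1] * (voxels[, 2] + shape[2] * voxels[, 3])
}

# 6-neighbour adjacency among the ROI's voxels, as a list of integer
# vectors of 1-based ROI indices.
.neighborList <- function(roi) {
  vox <- roiVoxels(roi)
  sh <- gridShape(roiGrid(roi))
  key <- .linearIndex(vox, sh)
  lookup <- seq_len(nrow(vox))
  names(lookup) <- as.character(key)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  lapply(seq_len(nrow(vox)), function(v) {
    nb <- sweep(offs, 2, vox[v, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
      nb[, 1] < sh[1] & nb[, 2] < sh[2] & nb[, 3] < sh[3]
    nb <- nb[ok, , drop = FALSE]
    idx <- lookup[as.character(.linearIndex(nb, sh))]
    as.integer(idx[!is.na(idx)])
  })
}

# Connected components of a ROI under 6-adjacency (union-find).
.roiComponents <- function(roi) {
  nbrs <- .neighborList(roi)
  n <- roiSize(roi)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (v in seq_len(n)) for (w in nbrs[[v]]) {
    rv <- find(v); rw <- find(w)
    if (rv != rw) parent[rw] <- rv
  }
  vapply(seq_len(n), find, integer(1))
}
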
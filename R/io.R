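#' Read a NIfTI volume together with its grid geometry
#'
#' @param path path to a .nii/.nii.gz file.
#' @return list with \code{data} (array) and \code{grid} (a
#'   \code{VoxelGrid} built from the image's xform and 3-D dimensions).
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  d <- dim(img)
  grid <- VoxelGrid(d[1:3], affine = aff)
  list(data = unclass(img), grid = grid)
}

#' Write a 3-D volume as NIfTI on a given grid
#'
#' @param data 3-D array.
#' @param grid a \code{VoxelGrid} supplying the affine.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(data, grid, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxelSize(grid)
  aff <- structure(gridAffine(grid), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

.checkGridsMatch <- function(gridA, gridB, whatA, whatB, tol = 1e-6) {
  if (!identical(gridShape(gridA), gridShape(gridB)))
    stop("grid mismatch between ", whatA, " and ", whatB, ": shape ",
         paste(gridShape(gridA), collapse = "x"), " vs ",
         paste(gridShape(gridB), collapse = "x"))
  if (max(abs(gridAffine(gridA) - gridAffine(gridB))) > tol)
    stop("grid mismatch between ", whatA, " and ", whatB,
         ": affines differ by more than ", tol)
  invisible(TRUE)
}

# ROI from a label volume; voxel order is the deterministic raster order
# of the volume (ascending i, then j, then k -- column-major order).
.roiFromLabels <- function(labels, grid, label, name) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("label ", label, " selects no voxels in the label volume")
  ROIDefinition(name, idx - 1L, grid)
}

#' Extract ROI voxel time courses from a 4-D volume
#'
#' Row v of the result is the time course of the ROI's v-th voxel, so the
#' row order of every downstream connectivity matrix is fixed by the
#' \code{ROIDefinition}.
#'
#' @param volume4d 4-D array (i, j, k, t).
#' @param roi a \code{ROIDefinition}.
#' @param session session id to record (default 1).
#' @return A \code{SessionTimeSeries}.
#' @export
extractROITimeSeries <- function(volume4d, roi, session = 1L) {
  d <- dim(volume4d)
  if (length(d) != 4L) stop("volume4d must be a 4-D array")
  sh <- gridShape(roiGrid(roi))
  vox <- roiVoxels(roi)
  if (any(vox[, 1] >= d[1] | vox[, 2] >= d[2] | vox[, 3] >= d[3]))
    stop("ROI contains voxels outside the volume bounds")
  lin <- .linearIndex(vox, d[1:3]) + 1
  flat <- matrix(volume4d, nrow = prod(d[1:3]), ncol = d[4])
  SessionTimeSeries(session, flat[lin, , drop = FALSE])
}

#' Load the full two-session input set for one ROI pair
#'
#' Reads the two 4-D BOLD volumes and the integer label volume, checks that
#' all three share one grid (shape and affine equal within 1e-6), builds a
#' \code{ROIDefinition} per requested label in deterministic raster order,
#' and extracts one \code{SessionTimeSeries} per (ROI, session).
#'
#' @param session1Path,session2Path 4-D NIfTI paths, one per session.
#' @param labelsPath 3-D integer label volume on the same grid.
#' @param roiALabel,roiBLabel integer labels of the two ROIs.
#' @param roiNames character names for the two ROIs.
#' @return list with \code{grid}, \code{roiA}, \code{roiB}, \code{tsA1},
#'   \code{tsA2}, \code{tsB1}, \code{tsB2}.
#' @export
loadInputs <- function(session1Path, session2Path, labelsPath,
                       roiALabel, roiBLabel,
                       roiNames = c("roiA", "roiB")) {
  s1 <- readVolume(session1Path)
  s2 <- readVolume(session2Path)
  lab <- readVolume(labelsPath)
  .checkGridsMatch(s1$grid, s2$grid, "session 1", "session 2")
  .checkGridsMatch(s1$grid, lab$grid, "session 1", "label volume")
  grid <- s1$grid
  roiA <- .roiFromLabels(lab$data, grid, roiALabel, roiNames[1])
  roiB <- .roiFromLabels(lab$data, grid, roiBLabel, roiNames[2])
  out <- list(grid = grid, roiA = roiA, roiB = roiB,
              tsA1 = extractROITimeSeries(s1$data, roiA, 1L),
              tsA2 = extractROITimeSeries(s2$data, roiA, 2L),
              tsB1 = extractROITimeSeries(s1$data, roiB, 1L),
              tsB2 = extractROITimeSeries(s2$data, roiB, 2L))
  for (nm in c("tsA1", "tsA2", "tsB1", "tsB2")) {
    bad <- which(!apply(is.finite(tsData(out[[nm]])), 1, all))
    if (length(bad))
      stop("non-finite time series in ", nm, " for ROI voxel row(s) ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  out
}

#' Read / write ROI voxel tables
#'
#' Plain-text alternative to a label volume: a TSV with columns
#' \code{roi}, \code{i}, \code{j}, \code{k} (0-based voxel indices).
#'
#' @param path TSV path.
#' @param grid a \code{VoxelGrid} for the returned ROIs.
#' @return \code{readROITable}: named list of \code{ROIDefinition}s.
#' @export
readROITable <- function(path, grid) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("roi", "i", "j", "k") %in% names(tab)))
  lapply(split(tab, tab$roi), function(d)
    ROIDefinition(d$roi[1], cbind(d$i, d$j, d$k), grid))
}

#' @rdname readROITable
#' @param rois list of \code{ROIDefinition}s to write.
#' @export
writeROITable <- function(rois, path) {
  tab <- do.call(rbind, lapply(rois, function(r) {
    v <- roiVoxels(r)
    data.frame(roi = roiName(r), i = v[, 1], j = v[, 2], k = v[, 3])
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write detected sub-regional pairs as an integer label map
#'
#' Voxels belonging to the n-th surviving pair get label n (in both ROIs);
#' all other voxels are 0. Reading the map back with \code{readVolume}
#' recovers the exact voxel sets.
#'
#' @param result an \code{ECResult}.
#' @param roiA,roiB the \code{ROIDefinition}s the result refers to.
#' @param path output NIfTI path.
#' @return \code{path}, invisibly.
#' @export
writeSRPLabelMap <- function(result, roiA, roiB, path) {
  grid <- roiGrid(roiA)
  vol <- array(0L, dim = gridShape(grid))
  vA <- roiVoxels(roiA); vB <- roiVoxels(roiB)
  for (n in seq_along(srps(result))) {
    s <- srps(result)[[n]]
    vol[vA[membersA(s), , drop = FALSE] + 1L] <- n
    vol[vB[membersB(s), , drop = FALSE] + 1L] <- n
  }
  writeVolume(vol, grid, path)
}
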
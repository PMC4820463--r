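# ROI-tagged voxel set of one sub-regional pair: members of ROI-A keep
# their index, members of ROI-B are shifted by nA so a voxel of ROI-A can
# never collide with the same coordinate in ROI-B.
.taggedSet <- function(srp, nA) {
  c(srp@membersA, nA + srp@membersB)
}

.dice <- function(x, y) {
  2 * length(intersect(x, y)) / (length(x) + length(y))
}

#' Mean maximal Sorenson-dice overlap between two runs
#'
#' Every pair's voxel set is the ROI-tagged union of its two sub-regions.
#' For each pair detected in run 1 the maximal dice score against all
#' run-2 pairs is taken, and symmetrically for run 2; the result is the
#' mean over all these maxima (pairs from both runs included).
#'
#' @param srps1,srps2 lists of \code{SubRegionalPair}s (e.g.
#'   \code{srps()} of two \code{ECResult}s on the same ROI pair).
#' @param nA size of ROI-A (for tagging).
#' @return mean maximal dice in [0, 1], or NA when either run is empty.
#' @export
diceOverlapRuns <- function(srps1, srps2, nA) {
  if (length(srps1) == 0L || length(srps2) == 0L) return(NA_real_)
  sets1 <- lapply(srps1, .taggedSet, nA)
  sets2 <- lapply(srps2, .taggedSet, nA)
  best1 <- vapply(sets1, function(x)
    max(vapply(sets2, .dice, numeric(1), x = x)), numeric(1))
  best2 <- vapply(sets2, function(x)
    max(vapply(sets1, .dice, numeric(1), x = x)), numeric(1))
  mean(c(best1, best2))
}

# Voxel-pair labeling of one run: cell (a, b) of the |A| x |B| grid gets
# the index of the pair containing it (edge supports are disjoint by
# blocking) or 0.
.pairLabeling <- function(srpList, nA, nB) {
  lab <- matrix(0L, nA, nB)
  for (n in seq_along(srpList)) {
    s <- srpList[[n]]
    lab[s@membersA, s@membersB] <- n
  }
  as.vector(lab)
}

#' Adjusted Rand index between the voxel-pair labelings of two runs
#'
#' Every voxel pair (a, b) in A x B is labeled 0 when it belongs to no
#' surviving sub-regional pair and by its pair's index otherwise; the
#' standard permutation-invariant adjusted Rand index is computed between
#' the two labelings.
#'
#' @param srps1,srps2 lists of \code{SubRegionalPair}s from two runs.
#' @param nA,nB the two ROI sizes.
#' @return ARI in (-1, 1].
#' @export
ariVoxelPairLabelings <- function(srps1, srps2, nA, nB) {
  mclust::adjustedRandIndex(.pairLabeling(srps1, nA, nB),
                            .pairLabeling(srps2, nA, nB))
}

#' Voxel-pair membership consistency across runs
#'
#' For each voxel pair, binary membership (inside any surviving
#' sub-regional pair vs not) is recorded per run; for every unordered pair
#' of runs the percentage of voxel pairs with equal membership is
#' computed, and the mean over run pairs returned.
#'
#' @param runs list (length >= 2) of lists of \code{SubRegionalPair}s.
#' @param nA,nB the two ROI sizes.
#' @return mean pairwise agreement percentage in [0, 100].
#' @export
voxelPairConsistency <- function(runs, nA, nB) {
  if (length(runs) < 2L) stop("need at least 2 runs")
  member <- lapply(runs, function(r) .pairLabeling(r, nA, nB) > 0L)
  pairs <- utils::combn(length(runs), 2)
  agree <- apply(pairs, 2, function(p)
    100 * mean(member[[p[1]]] == member[[p[2]]]))
  mean(agree)
}

#' Summarize run-to-run reliability of the search
#'
#' Computes, over all unordered pairs of the supplied runs, the mean
#' maximal dice overlap, the mean and standard deviation of the adjusted
#' Rand index of the voxel-pair labelings, and the voxel-pair membership
#' consistency.
#'
#' @param results list (length >= 2) of \code{ECResult}s on the same ROI
#'   pair.
#' @return list with \code{diceMean}, \code{ariMean}, \code{ariSd},
#'   \code{consistencyPct}, \code{nRunPairs}.
#' @export
compareRuns <- function(results) {
  if (length(results) < 2L) stop("need at least 2 runs")
  dims <- results[[1]]@dims
  runs <- lapply(results, srps)
  pairs <- utils::combn(length(runs), 2)
  dice <- apply(pairs, 2, function(p)
    diceOverlapRuns(runs[[p[1]]], runs[[p[2]]], dims[1]))
  ari <- apply(pairs, 2, function(p)
    ariVoxelPairLabelings(runs[[p[1]]], runs[[p[2]]], dims[1], dims[2]))
  list(diceMean = mean(dice, na.rm = TRUE),
       ariMean = mean(ari), ariSd = stats::sd(ari),
       consistencyPct = voxelPairConsistency(runs, dims[1], dims[2]),
       nRunPairs = ncol(pairs))
}
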
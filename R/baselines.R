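#' ROI-averaging connectivity baseline
#'
#' The conventional definition of the functional relationship between two
#' ROIs: average the BOLD signal over voxels per time point in each ROI,
#' correlate the two mean series, and Fisher z-transform the result.
#'
#' @param tsA,tsB \code{SessionTimeSeries} for the two ROIs, same T.
#' @return list with \code{r}, \code{fisherZ} (atanh(r), infinite when
#'   |r| = 1) and \code{degenerate} (TRUE when a mean series is constant,
#'   in which case r and fisherZ are NA).
#' @export
averagingConnectivity <- function(tsA, tsB) {
  A <- tsData(tsA); B <- tsData(tsB)
  if (ncol(A) != ncol(B)) stop("sessions have differing numbers of volumes")
  mA <- colMeans(A); mB <- colMeans(B)
  if (stats::sd(mA) == 0 || stats::sd(mB) == 0)
    return(list(r = NA_real_, fisherZ = NA_real_, degenerate = TRUE))
  r <- stats::cor(mA, mB)
  list(r = r, fisherZ = atanh(r), degenerate = FALSE)
}

#' Simple voxel-level edge-count baseline
#'
#' Total-edge-count plasticity: the absolute net change in the number of
#' 1-cells between the two session matrices (gl2). Cancelling gains and
#' losses inside the ROI pair can drive gl2 toward zero even when
#' substantial localized plasticity exists, which is the scenario the
#' sub-regional search is designed to expose.
#'
#' @param M1,M2 session \code{BinaryConnectivityMatrix} or 0/1 matrices of
#'   equal dimension.
#' @return list with \code{count1}, \code{count2}, \code{gl2}.
#' @export
edgeCountChange <- function(M1, M2) {
  if (is(M1, "BinaryConnectivityMatrix")) M1 <- connMatrix(M1)
  if (is(M2, "BinaryConnectivityMatrix")) M2 <- connMatrix(M2)
  if (!identical(dim(M1), dim(M2))) stop("matrix dimensions differ")
  c1 <- sum(M1); c2 <- sum(M2)
  list(count1 = c1, count2 = c2, gl2 = abs(c2 - c1))
}

#' Group-level reporting utilities for baseline statistics
#'
#' Thin wrappers over the standard tests used to compare per-subject
#' session statistics: a paired t-test on Fisher z-transformed
#' correlations, a paired Wilcoxon signed-rank test on edge counts, and a
#' Wilcoxon rank-sum comparison of plasticity estimates between two
#' groups with a Shapiro-Wilk normality screen.
#'
#' @param session1,session2 per-subject statistics (correlations for
#'   \code{pairedFisherZTest}, edge counts for
#'   \code{pairedEdgeCountTest}).
#' @return the underlying \code{htest} object.
#' @export
pairedFisherZTest <- function(session1, session2) {
  stats::t.test(atanh(session1), atanh(session2), paired = TRUE)
}

#' @rdname pairedFisherZTest
#' @export
pairedEdgeCountTest <- function(session1, session2) {
  stats::wilcox.test(session1, session2, paired = TRUE, exact = FALSE)
}

#' @rdname pairedFisherZTest
#' @param groupA,groupB per-subject plasticity estimates for two groups.
#' @return \code{groupPlasticityTest}: list with the rank-sum
#'   \code{htest} and the two Shapiro-Wilk screens.
#' @export
groupPlasticityTest <- function(groupA, groupB) {
  list(ranksum = stats::wilcox.test(groupA, groupB, exact = FALSE),
       shapiroA = stats::shapiro.test(groupA),
       shapiroB = stats::shapiro.test(groupB))
}
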
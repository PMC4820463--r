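#' Pearson correlation with a two-sided p-value
#'
#' Computes r and the two-sided p-value from the exact t transform
#' t = r * sqrt(T - 2) / sqrt(1 - r^2) on T - 2 degrees of freedom.
#' A zero-variance series is flagged degenerate (r and p are NA); callers
#' treat degenerate cells as "no edge".
#'
#' @param x,y numeric series of equal length T >= 3.
#' @return list with \code{r}, \code{p}, \code{degenerate}.
#' @examples
#' pearsonWithPvalue(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @export
pearsonWithPvalue <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
  r <- stats::cor(x, y)
  p <- .pvalFromR(r, n)
  list(r = r, p = p, degenerate = FALSE)
}

# Vectorized two-sided p from the t transform; |r| = 1 gives p = 0.
.pvalFromR <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  p <- rep(0, length(r))
  inside <- abs(r) < 1
  tt <- r[inside] * sqrt(n - 2) / sqrt(1 - r[inside]^2)
  p[inside] <- 2 * stats::pt(-abs(tt), df = n - 2)
  if (is.matrix(r)) p <- matrix(p, nrow(r), ncol(r))
  p
}

#' Benjamini-Hochberg FDR survival mask
#'
#' Step-up procedure: sort p ascending, find the largest k with
#' p(k) <= k * q / m and mark every hypothesis with p <= p(k) as
#' surviving; if no such k exists nothing survives.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (no NAs).
#' @param q FDR level in (0, 1).
#' @return logical vector, TRUE where the hypothesis survives.
#' @examples
#' bhFdrMask(c(0.01, 0.02, 0.04, 0.2), 0.05)
#' @export
bhFdrMask <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  # literal step-up on the sorted p-values; equivalent to thresholding
  # stats::p.adjust(..., "BH") at q except at exact floating-point
  # boundary hits p(k) == k*q/m, where the comparison is done on the p
  # scale as stated
  m <- length(pvalues)
  ps <- sort(pvalues)
  ks <- which(ps <= seq_len(m) * q / m)
  if (length(ks) == 0L) return(rep(FALSE, m))
  pvalues <= ps[max(ks)]
}

#' Build the binary connectivity matrix for one session
#'
#' All |A| x |B| voxel-pair Pearson correlations are computed; the BH step-up
#' FDR mask at level q is applied over the full family of p-values; cells
#' that fail FDR or have r <= 0 are set to 0 and the survivors to 1.
#' Zero-variance voxels contribute no edges (logged as a warning).
#'
#' @param tsA,tsB \code{SessionTimeSeries} for the two ROIs, same session
#'   and same T.
#' @param q FDR level (default 0.05).
#' @return A \code{BinaryConnectivityMatrix}.
#' @export
buildBinaryMatrix <- function(tsA, tsB, q = 0.05) {
  A <- tsData(tsA); B <- tsData(tsB)
  if (ncol(A) != ncol(B)) stop("sessions have differing numbers of volumes")
  if (sessionId(tsA) != sessionId(tsB)) stop("session ids differ")
  n <- ncol(A)
  sdA <- apply(A, 1, stats::sd)
  sdB <- apply(B, 1, stats::sd)
  degA <- sdA == 0; degB <- sdB == 0
  if (any(degA) || any(degB))
    warning(sum(degA), " ROI-A and ", sum(degB),
            " ROI-B zero-variance voxel(s); their cells carry no edges")
  R <- matrix(0, nrow(A), ncol = nrow(B))
  okA <- which(!degA); okB <- which(!degB)
  if (length(okA) && length(okB)) {
    R[okA, okB] <- stats::cor(t(A[okA, , drop = FALSE]),
                              t(B[okB, , drop = FALSE]))
    P <- .pvalFromR(R[okA, okB, drop = FALSE], n)
    surv <- bhFdrMask(as.vector(P), q)
    M <- matrix(0, nrow(A), nrow(B))
    sub <- matrix(0, length(okA), length(okB))
    sub[surv & as.vector(R[okA, okB, drop = FALSE] > 0)] <- 1
    M[okA, okB] <- sub
  } else {
    M <- matrix(0, nrow(A), nrow(B))
  }
  BinaryConnectivityMatrix(sessionId(tsA), M, n)
}
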
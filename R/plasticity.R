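#' Subject-level positive/negative plasticity estimate
#'
#' Gains are summed over surviving pairs with NC2 > NC1 and losses over
#' pairs with NC2 < NC1; each is expressed as a percentage of the total
#' possible voxel-wise connections |A| x |B| between the ROI pair, and
#' gl1 = gains + losses is the overall edges gained/lost. Because the
#' recursive search blocks the edges of every detected pair, edge supports
#' are disjoint and the two percentages can never sum above 100.
#'
#' @param x an \code{ECResult}, a list of \code{SubRegionalPair}s, or a
#'   data.frame with columns \code{NC1} and \code{NC2} (one row per
#'   surviving pair).
#' @param nA,nB the two ROI sizes in voxels.
#' @return A \code{PlasticityEstimate}.
#' @examples
#' estimatePlasticity(data.frame(NC1 = c(0, 0, 5000),
#'                               NC2 = c(10000, 1000, 0)), 100, 500)
#' @export
estimatePlasticity <- function(x, nA, nB) {
  total <- as.numeric(nA) * as.numeric(nB)
  if (total <= 0) stop("ROI sizes must be positive")
  if (is(x, "ECResult")) x <- srps(x)
  if (is.data.frame(x)) {
    nc1 <- x$NC1; nc2 <- x$NC2
  } else {
    nc1 <- vapply(x, function(s) s@NC1, numeric(1))
    nc2 <- vapply(x, function(s) s@NC2, numeric(1))
  }
  delta <- nc2 - nc1
  gains <- sum(delta[delta > 0])
  losses <- -sum(delta[delta < 0])
  new("PlasticityEstimate",
      pctPositive = 100 * gains / total,
      pctNegative = 100 * losses / total,
      gl1 = gains + losses, totalPossible = total)
}
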
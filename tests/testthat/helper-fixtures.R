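# Shared fixtures and independent oracles for the test suite.

# A ROI from an explicit 0-based voxel list on a fresh grid.
roiFromList <- function(vox, shape = c(6, 6, 6), name = "roi",
                        voxelSize = c(3, 3, 3)) {
  ROIDefinition(name, vox, VoxelGrid(shape, voxelSize = voxelSize))
}

# Straight line of n voxels along i at (j, k) = (0, 0).
lineROI <- function(n, shape = c(max(n, 2), 2, 2), name = "line") {
  roiFromList(cbind(0:(n - 1), 0L, 0L), shape, name)
}

# Plus-shaped 5-voxel ROI in the k = 0 plane, centered at (2, 2, 0):
# used for hand-derivable BFS orderings.
plusROI <- function(name = "plus") {
  roiFromList(rbind(c(2, 2, 0), c(1, 2, 0), c(3, 2, 0),
                    c(2, 1, 0), c(2, 3, 0)), c(5, 5, 2), name)
}

# Independent union-find connectivity check on a member set: TRUE when
# the members form one 6-connected component.
isConnectedSet <- function(roi, members) {
  vox <- roiVoxels(roi)[members, , drop = FALSE]
  n <- nrow(vox)
  if (n == 1L) return(TRUE)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (sum(abs(vox[a, ] - vox[b, ])) == 1L) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

# Brute-force Benjamini-Hochberg step-up: the literal textbook recipe,
# independent of stats::p.adjust.
bhStepUpOracle <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * q / m)
  if (length(ks) == 0L) return(rep(FALSE, m))
  thr <- ps[max(ks)]
  p <= thr
}

# Exhaustive enumeration of every decodable sub-regional pair on a toy
# ROI pair with lattice {1, 2, ...}: returns the distinct decoded pairs
# and the brute-force maximal fitness.
enumeratePairs <- function(roiA, roiB, M1, M2) {
  subsOf <- function(roi) {
    sigs <- character(0); subs <- list()
    for (root in seq_len(roiSize(roi))) for (L in 1:roiSize(roi)) {
      m <- growSubregionBFS(root, roi, L)
      s <- paste(m, collapse = ",")
      if (!s %in% sigs) { sigs <- c(sigs, s); subs <- c(subs, list(m)) }
    }
    subs
  }
  subsA <- subsOf(roiA); subsB <- subsOf(roiB)
  bestFit <- -Inf
  for (mA in subsA) for (mB in subsB) {
    f <- fitnessZscore(sum(M1[mA, mB]), sum(M2[mA, mB]),
                       length(mA) * length(mB))
    if (f$fitness > bestFit) bestFit <- f$fitness
  }
  list(nPairs = length(subsA) * length(subsB), maxFitness = bestFit)
}

# Tagged dice between a detected pair and a planted block.
taggedDice <- function(srp, block, nA) {
  x <- c(membersA(srp), nA + membersB(srp))
  y <- c(block$membersA, nA + block$membersB)
  2 * length(intersect(x, y)) / (length(x) + length(y))
}

# Small planted-gain matrix scenario reused by recovery tests: two
# connected 40-voxel ROIs, one 18x18 block going 0.05 -> 0.9 over a 0.03
# background.
plantedGainScenario <- function(seed) {
  set.seed(seed)
  geo <- makeGeometry(c(8, 8, 8), c(40, 40))
  block <- plantBlock(geo$roiA, geo$roiB, 18, 18, d1 = 0.05, d2 = 0.9)
  truth <- plantedTruth(list(block), background = 0.03)
  ds <- makeMatrixDataset(truth, geo$roiA, geo$roiB)
  list(geo = geo, block = block, ds = ds)
}

toyConfig <- function(seed, populationSize = 60L, stall = 20L, ...) {
  ECConfig(populationSize = populationSize, lMin = 1L, lStep = 1L,
           stallGenerations = stall, seed = seed, ...)
}
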
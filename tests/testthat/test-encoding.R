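test_that("decodeRootVoxel picks the nearest center with the z,y,x tie-break", {
  roi <- plusROI()
  centers <- voxelCenters(roiGrid(roi), roiVoxels(roi))
  # a point exactly at a center decodes to that voxel
  for (v in seq_len(roiSize(roi)))
    expect_equal(decodeRootVoxel(centers[v, ], roi), v)
  # equidistant points break ties toward smaller y (here z is constant)
  roiY <- roiFromList(rbind(c(1, 1, 0), c(1, 3, 0)), c(4, 5, 2))
  cy <- voxelCenters(roiGrid(roiY), roiVoxels(roiY))
  expect_equal(decodeRootVoxel(colMeans(cy), roiY), 1)
  # tie along z
  roiZ <- roiFromList(rbind(c(1, 1, 0), c(1, 1, 2)), c(3, 3, 3))
  cz <- voxelCenters(roiGrid(roiZ), roiVoxels(roiZ))
  expect_equal(decodeRootVoxel(colMeans(cz), roiZ), 1)
})

test_that("decodeRootVoxel agrees with an exhaustive distance scan", {
  set.seed(11)
  geo <- makeGeometry(c(6, 6, 6), c(20, 15))
  roi <- geo$roiA
  centers <- voxelCenters(roiGrid(roi), roiVoxels(roi))
  for (rep in 1:50) {
    p <- runif(3, min = apply(centers, 2, min),
               max = apply(centers, 2, max))
    d <- sqrt(colSums((t(centers) - p)^2))
    expect_equal(decodeRootVoxel(p, roi), which.min(d))
  }
})

test_that("BFS growth is deterministic with the z,y,x frontier order", {
  roi <- plusROI()   # root 1 at (2,2,0); arms at (1,2),(3,2),(2,1),(2,3)
  # neighbours of the center, sorted ascending (z, y, x):
  # (2,1,0) [idx 4], (1,2,0) [idx 2], (3,2,0) [idx 3], (2,3,0) [idx 5]
  expect_equal(growSubregionBFS(1, roi, 0), 1)
  expect_equal(growSubregionBFS(1, roi, 1), sort(c(1, 4)))
  expect_equal(growSubregionBFS(1, roi, 2), sort(c(1, 4, 2)))
  expect_equal(growSubregionBFS(1, roi, 3), sort(c(1, 4, 2, 3)))
  expect_equal(growSubregionBFS(1, roi, 4), 1:5)
  # L beyond the ROI size returns the whole component
  expect_equal(growSubregionBFS(1, roi, 99), 1:5)
  expect_error(growSubregionBFS(9, roi, 1), "root")
})

test_that("disconnected ROIs cap growth at the root's component", {
  roi <- roiFromList(rbind(c(0, 0, 0), c(1, 0, 0), c(4, 4, 4)),
                     c(6, 6, 6))
  expect_equal(growSubregionBFS(1, roi, 10), c(1, 2))
  expect_equal(growSubregionBFS(3, roi, 10), 3)
})

test_that("decoded sub-regions are connected and monotone in L", {
  set.seed(12)
  geo <- makeGeometry(c(7, 7, 7), c(30, 30))
  for (rep in 1:20) {
    root <- sample.int(30, 1)
    prev <- integer(0)
    for (L in c(0, 1, 3, 7, 15, 29)) {
      m <- growSubregionBFS(root, geo$roiA, L)
      expect_true(isConnectedSet(geo$roiA, m))
      expect_true(all(prev %in% m))     # monotone non-decreasing in L
      expect_lte(length(m), L + 1)
      prev <- m
    }
  }
})

test_that("decoding factors through the root and is a pure function", {
  set.seed(13)
  geo <- makeGeometry(c(6, 6, 6), c(15, 12))
  centers <- voxelCenters(geo$grid, roiVoxels(geo$roiA))
  # two points with the same nearest voxel decode identically
  c1 <- centers[5, ] + c(0.2, -0.3, 0.1)
  c2 <- centers[5, ] + c(-0.4, 0.2, 0.3)
  rootB <- voxelCenters(geo$grid, roiVoxels(geo$roiB))[1, ]
  p1 <- decodeChromosome(c(c1, 3, rootB, 2), geo$roiA, geo$roiB)
  p2 <- decodeChromosome(c(c2, 3, rootB, 2), geo$roiA, geo$roiB)
  expect_identical(membersA(p1), membersA(p2))
  expect_identical(membersB(p1), membersB(p2))
  # same chromosome twice: identical decode
  ch <- c(centers[7, ], 4, rootB, 3)
  expect_identical(membersA(decodeChromosome(ch, geo$roiA, geo$roiB)),
                   membersA(decodeChromosome(ch, geo$roiA, geo$roiB)))
})

test_that("decodeChromosome matches an independent nearest+BFS reimplementation", {
  set.seed(14)
  geo <- makeGeometry(c(6, 6, 6), c(18, 14))
  # independent oracle: plain-R nearest neighbour + list-based BFS
  oracleDecode <- function(point, roi, L) {
    centers <- voxelCenters(roiGrid(roi), roiVoxels(roi))
    d <- sqrt(colSums((t(centers) - point)^2))
    cand <- which(abs(d - min(d)) <= 1e-9)
    cand <- cand[order(centers[cand, 3], centers[cand, 2],
                       centers[cand, 1])]
    root <- cand[1]
    vox <- roiVoxels(roi)
    queue <- root; members <- root; visited <- root
    while (length(queue) && (length(members) - 1) < L) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(vapply(seq_len(nrow(vox)), function(w)
        sum(abs(vox[w, ] - vox[v, ])) == 1, logical(1)))
      nb <- setdiff(nb, visited)
      nb <- nb[order(centers[nb, 3], centers[nb, 2], centers[nb, 1])]
      for (w in nb) {
        if ((length(members) - 1) < L) members <- c(members, w)
        visited <- c(visited, w)
        queue <- c(queue, w)
      }
    }
    sort(members)
  }
  cA <- voxelCenters(geo$grid, roiVoxels(geo$roiA))
  cB <- voxelCenters(geo$grid, roiVoxels(geo$roiB))
  for (rep in 1:15) {
    pA <- runif(3, apply(cA, 2, min), apply(cA, 2, max))
    pB <- runif(3, apply(cB, 2, min), apply(cB, 2, max))
    # the size gene is a 0-based lattice index; with lattice {1..n} the
    # decoded L is gene + 1
    gA <- sample(0:16, 1); gB <- sample(0:12, 1)
    got <- decodeChromosome(c(pA, gA, pB, gB), geo$roiA, geo$roiB)
    expect_identical(membersA(got),
                     as.integer(oracleDecode(pA, geo$roiA, gA + 1)))
    expect_identical(membersB(got),
                     as.integer(oracleDecode(pB, geo$roiB, gB + 1)))
  }
})

test_that("maximal L genes decode to the full connected component", {
  set.seed(15)
  geo <- makeGeometry(c(6, 6, 6), c(16, 10))
  cA <- voxelCenters(geo$grid, roiVoxels(geo$roiA))[1, ]
  cB <- voxelCenters(geo$grid, roiVoxels(geo$roiB))[1, ]
  p <- decodeChromosome(c(cA, 15, cB, 9), geo$roiA, geo$roiB)
  expect_identical(membersA(p), seq_len(16L))
  expect_identical(membersB(p), seq_len(10L))
})
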
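test_that("fitnessZscore reproduces hand-evaluated binomial z-scores", {
  f <- fitnessZscore(100, 150, 1000)
  expect_equal(f$SD, sqrt(90), tolerance = 1e-12)
  expect_equal(f$fitness, 50 / sqrt(90), tolerance = 1e-12)
  expect_equal(f$fitness, 5.2705, tolerance = 1e-4)
  expect_equal(f$sign, 1L)
  expect_equal(f$EC2, 100)
  f2 <- fitnessZscore(200, 120, 400)
  expect_equal(f2$SD, 10)
  expect_equal(f2$fitness, 8)
  expect_equal(f2$sign, -1L)
  # no change means zero fitness for any counts
  for (nc in c(1, 57, 399)) {
    f0 <- fitnessZscore(nc, nc, 400)
    expect_equal(f0$fitness, 0)
    expect_equal(f0$sign, 0L)
  }
  expect_error(fitnessZscore(1, 1, 0), "TC")
  expect_error(fitnessZscore(-1, 0, 10), "edge counts")
})

test_that("degenerate session-1 rates use the continuity correction", {
  # NC1 = 0: P1 clamped to 0.5/TC
  f <- fitnessZscore(0, 10, 100)
  P1c <- 0.5 / 100
  expect_equal(f$EC2, 0.5)
  expect_equal(f$SD, sqrt(100 * P1c * (1 - P1c)), tolerance = 1e-12)
  expect_equal(f$Z, (10 - 0.5) / f$SD, tolerance = 1e-12)
  expect_gt(f$fitness, 0)
  # NC1 = TC with NC2 = NC1 stays at zero fitness
  expect_equal(fitnessZscore(100, 100, 100)$fitness, 0)
  expect_equal(fitnessZscore(0, 0, 50)$fitness, 0)
})

test_that("countConnections equals a nested-loop recount", {
  set.seed(21)
  M <- matrix(rbinom(12 * 9, 1, 0.4), 12, 9)
  expect_equal(countConnections(1:3, 1:4, matrix(0, 5, 5)), 0)
  expect_equal(countConnections(1:3, 1:4, matrix(1, 5, 5)), 12)
  for (rep in 1:10) {
    mA <- sample.int(12, sample(1:6, 1))
    mB <- sample.int(9, sample(1:5, 1))
    slow <- 0
    for (a in mA) for (b in mB) slow <- slow + M[a, b]
    expect_equal(countConnections(mA, mB, M), slow)
  }
})

test_that("mutation respects offset ranges, cuboid clamping and identity", {
  set.seed(22)
  geo <- makeGeometry(c(8, 8, 8), c(40, 30))
  cfg <- toyConfig(1)
  centers <- voxelCenters(geo$grid, roiVoxels(geo$roiA))
  lo <- apply(centers, 2, min); hi <- apply(centers, 2, max)
  parent <- c(pmin(pmax(c(10, 10, 10), lo), hi), 5,
              voxelCenters(geo$grid, roiVoxels(geo$roiB))[3, ], 4)
  kids <- t(replicate(1000, mutateChromosome(parent, geo$roiA, geo$roiB,
                                             cfg)))
  # child X1 within [x - 6, x + 6] intersected with the cuboid
  expect_true(all(kids[, 1] >= max(parent[1] - 6, lo[1]) - 1e-9))
  expect_true(all(kids[, 1] <= min(parent[1] + 6, hi[1]) + 1e-9))
  expect_true(all(kids[, 1] >= lo[1] & kids[, 1] <= hi[1]))
  # size-gene lattice index moves at most dl = 4 steps and stays in range
  expect_true(all(abs(kids[, 4] - 5) <= 4))
  expect_true(all(kids[, 4] >= 0 & kids[, 4] <= 39))
  # parent at the cuboid boundary never escapes
  pb <- c(lo, 0, apply(voxelCenters(geo$grid, roiVoxels(geo$roiB)), 2,
                       min), 0)
  kb <- t(replicate(200, mutateChromosome(pb, geo$roiA, geo$roiB, cfg)))
  expect_true(all(kb[, 1] >= lo[1] & kb[, 2] >= lo[2] & kb[, 3] >= lo[3]))
  # zero offsets give an identical decode
  cfg0 <- ECConfig(populationSize = 4, offsetMm = 0, dl = 0, lMin = 1,
                   lStep = 1)
  k0 <- mutateChromosome(parent, geo$roiA, geo$roiB, cfg0)
  a <- decodeChromosome(parent, geo$roiA, geo$roiB)
  b <- decodeChromosome(k0, geo$roiA, geo$roiB)
  expect_identical(membersA(a), membersA(b))
  expect_identical(membersB(a), membersB(b))
})

test_that("population-elitist selection keeps the top half, stably", {
  expect_equal(sort(c(5, 4, 3, 2, 1, 0)[selectPopulationElitist(
    c(5, 4, 3, 2, 1, 0), 3)]), c(3, 4, 5))
  # all-equal fitness: first n in stable pool order (parents first)
  expect_equal(selectPopulationElitist(rep(1, 6), 3), 1:3)
  # ties at the cutoff go to the earlier pool position
  expect_equal(selectPopulationElitist(c(2, 1, 1, 1), 2), c(1, 2))
  # random pools agree with a full sort-and-slice oracle
  set.seed(23)
  for (rep in 1:20) {
    f <- sample(0:5, 12, replace = TRUE) + runif(12) * 0.01
    keep <- selectPopulationElitist(f, 6)
    expect_equal(sort(f[keep], decreasing = TRUE),
                 sort(f, decreasing = TRUE)[1:6])
  }
})

test_that("identical matrices give zero best fitness", {
  set.seed(24)
  geo <- makeGeometry(c(6, 6, 6), c(15, 15))
  M <- matrix(rbinom(15 * 15, 1, 0.3), 15, 15)
  set.seed(1)
  res <- runECLevel(M, M, geo$roiA, geo$roiB, toyConfig(1, 30L, 10L))
  expect_equal(res$srp@fitness, 0)
  expect_lt(res$srp@fitness, 1)  # below the recursion stop threshold
})

test_that("the search recovers a planted block and its statistics check out", {
  sc <- plantedGainScenario(31)
  cfg <- toyConfig(7, 120L, 25L)
  res <- detectAllSRPs(sc$ds$M1, sc$ds$M2, sc$geo$roiA, sc$geo$roiB, cfg)
  expect_gte(length(srps(res)), 1)
  best <- srps(res)[[1]]
  expect_equal(best@sign, 1L)
  expect_gte(taggedDice(best, sc$block, 40), 0.6)
  # bookkeeping invariants on every detected pair
  for (s in detectedPairs(res)) {
    expect_equal(s@TC, length(membersA(s)) * length(membersB(s)))
    expect_equal(s@fitness, abs(s@Z))
    expect_equal(s@sign, as.integer(sign(s@NC2 - s@NC1)))
    expect_true(isConnectedSet(sc$geo$roiA, membersA(s)))
    expect_true(isConnectedSet(sc$geo$roiB, membersB(s)))
  }
})

test_that("EC best fitness never exceeds the exhaustive maximum and attains it", {
  set.seed(25)
  geo <- makeGeometry(c(5, 5, 3), c(6, 5))
  M1 <- matrix(rbinom(30, 1, 0.3), 6, 5)
  M2 <- matrix(rbinom(30, 1, 0.6), 6, 5)
  oracle <- enumeratePairs(geo$roiA, geo$roiB, M1, M2)
  npop <- 2 * ceiling(oracle$nPairs / 2)
  hits <- 0
  for (sd in 1:3) {
    cfg <- toyConfig(sd, npop, 10L)
    set.seed(sd)
    res <- runECLevel(M1, M2, geo$roiA, geo$roiB, cfg)
    expect_lte(res$srp@fitness, oracle$maxFitness + 1e-9)
    if (abs(res$srp@fitness - oracle$maxFitness) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("detectAllSRPs is bit-identical under a fixed seed", {
  sc <- plantedGainScenario(32)
  cfg <- toyConfig(5, 80L, 12L)
  r1 <- detectAllSRPs(sc$ds$M1, sc$ds$M2, sc$geo$roiA, sc$geo$roiB, cfg)
  r2 <- detectAllSRPs(sc$ds$M1, sc$ds$M2, sc$geo$roiA, sc$geo$roiB, cfg)
  expect_identical(r1@generationsRun, r2@generationsRun)
  expect_identical(r1@bestFitnessTrace, r2@bestFitnessTrace)
  expect_equal(length(srps(r1)), length(srps(r2)))
  for (i in seq_along(srps(r1))) {
    expect_identical(membersA(srps(r1)[[i]]), membersA(srps(r2)[[i]]))
    expect_identical(membersB(srps(r1)[[i]]), membersB(srps(r2)[[i]]))
    expect_identical(srps(r1)[[i]]@Z, srps(r2)[[i]]@Z)
  }
})

test_that("best-ever fitness traces are monotone non-decreasing", {
  sc <- plantedGainScenario(33)
  cfg <- toyConfig(2, 60L, 10L)
  res <- detectAllSRPs(sc$ds$M1, sc$ds$M2, sc$geo$roiA, sc$geo$roiB, cfg)
  for (tr in res@bestFitnessTrace)
    expect_true(all(diff(tr) >= 0))
})

test_that("blocking leaves recorded pairs with no edges and disjoint supports", {
  sc <- plantedGainScenario(34)
  cfg <- toyConfig(3, 80L, 12L)
  res <- detectAllSRPs(sc$ds$M1, sc$ds$M2, sc$geo$roiA, sc$geo$roiB, cfg)
  det <- detectedPairs(res)
  expect_gte(length(det), 1)
  M1w <- connMatrix(sc$ds$M1); M2w <- connMatrix(sc$ds$M2)
  support <- matrix(FALSE, 40, 40)
  for (s in det) {
    # supports are pairwise disjoint
    expect_false(any(support[membersA(s), membersB(s)]))
    support[membersA(s), membersB(s)] <- TRUE
    M1w[membersA(s), membersB(s)] <- 0
    M2w[membersA(s), membersB(s)] <- 0
  }
  # re-evaluating any recorded pair on the blocked matrices gives zero
  for (s in det) {
    nc1 <- countConnections(membersA(s), membersB(s), M1w)
    nc2 <- countConnections(membersA(s), membersB(s), M2w)
    expect_equal(nc1 + nc2, 0)
    expect_equal(fitnessZscore(nc1, nc2, s@TC)$fitness, 0)
  }
  # summed |NC2 - NC1| can never exceed the matrix size
  expect_lte(sum(vapply(det, function(s) abs(s@NC2 - s@NC1), numeric(1))),
             1600)
})

test_that("Bonferroni correction uses the recorded-pair count", {
  mk <- function(z) {
    s <- decodeChromosome(c(0, 0, 0, 1, 0, 0, 0, 1),
                          lineROI(4, name = "a"), lineROI(4, name = "b"))
    s@Z <- z
    s
  }
  tenpairs <- c(lapply(rep(3.29, 9), mk), list(mk(2.575)))
  # p_raw ~0.001 with m = 10 -> ~0.01, kept; p_raw ~0.01 -> 0.1, dropped
  out <- bonferroniFilter(tenpairs, 0.05)
  expect_equal(length(out$all), 10)
  expect_equal(length(out$survivors), 9)
  expect_equal(out$all[[1]]@pCorrected, 10 * out$all[[1]]@pRaw)
  expect_gt(out$all[[10]]@pCorrected, 0.05)
  # the normal tail matches an independent erfc evaluation
  f <- fitnessZscore(100, 150, 1000)
  pRaw <- bonferroniFilter(list(mk(f$Z)), 0.05)$all[[1]]@pRaw
  expect_equal(pRaw, pracma::erfc(abs(f$Z) / sqrt(2)),
               tolerance = 1e-9)
})

test_that("population size stays constant across generations", {
  # the selection contract: pool of size n * (1 + offspring) cut back to n
  set.seed(26)
  for (n in c(4, 10)) {
    f <- runif(2 * n)
    expect_length(selectPopulationElitist(f, n), n)
  }
  # and end-to-end: a level on a toy problem completes with the configured
  # population (indirectly: determinism + bounded generations)
  geo <- makeGeometry(c(5, 5, 3), c(8, 8))
  M1 <- matrix(0, 8, 8); M2 <- matrix(0, 8, 8); M2[1:3, 1:3] <- 1
  set.seed(1)
  res <- runECLevel(M1, M2, geo$roiA, geo$roiB, toyConfig(1, 20L, 8L))
  expect_gte(res$srp@fitness, 0)
  expect_lte(res$generations, 8L + length(res$trace))
})
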
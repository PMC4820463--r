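#' Binomial-test z-score fitness of an edge-count change
#'
#' The session-1 edge fraction P1 = NC1/TC is taken as the null rate for
#' session 2: EC2 = P1 * TC, SD = sqrt(TC * P1 * (1 - P1)),
#' Z = (NC2 - EC2)/SD, and the fitness is |Z|. When P1 is 0 or 1 the
#' binomial SD vanishes; P1 is then clamped to [0.5/TC, 1 - 0.5/TC]
#' (continuity correction) before the formulas are applied, and if
#' additionally NC2 = NC1 the fitness is 0, preserving "no change, zero
#' fitness" while letting total gain or loss from an empty or full
#' baseline score very high.
#'
#' @param NC1,NC2 edge counts at sessions 1 and 2, in [0, TC].
#' @param TC total possible connections, >= 1.
#' @return list with \code{Z} (signed), \code{fitness} (= |Z|),
#'   \code{EC2}, \code{SD}, \code{sign} (= sign(NC2 - NC1)).
#' @examples
#' fitnessZscore(100, 150, 1000)
#' @export
fitnessZscore <- function(NC1, NC2, TC) {
  if (TC < 1) stop("TC must be >= 1 (empty sub-regions cannot occur)")
  if (NC1 < 0 || NC2 < 0 || NC1 > TC || NC2 > TC)
    stop("edge counts must lie in [0, TC]")
  sgn <- as.integer(sign(NC2 - NC1))
  P1 <- NC1 / TC
  if (P1 <= 0 || P1 >= 1) {
    if (NC2 == NC1)
      return(list(Z = 0, fitness = 0, EC2 = NC1, SD = 0, sign = 0L))
    P1 <- min(max(P1, 0.5 / TC), 1 - 0.5 / TC)
  }
  EC2 <- P1 * TC
  SD <- sqrt(TC * P1 * (1 - P1))
  Z <- (NC2 - EC2) / SD
  list(Z = Z, fitness = abs(Z), EC2 = EC2, SD = SD, sign = sgn)
}

#' Count edges between a sub-regional pair
#'
#' Sum of the connectivity matrix over the |membersA| x |membersB|
#' submatrix.
#'
#' @param membersA,membersB 1-based member indices into the ROI rows.
#' @param M a \code{BinaryConnectivityMatrix} or plain 0/1 matrix.
#' @return integer edge count.
#' @export
countConnections <- function(membersA, membersB, M) {
  if (is(M, "BinaryConnectivityMatrix")) M <- connMatrix(M)
  sum(M[membersA, membersB, drop = FALSE])
}

#' Mutate a chromosome
#'
#' Each spatial gene is drawn uniformly from [g - offset, g + offset] and
#' clamped to its bounding cuboid; each size gene's lattice index is drawn
#' uniformly from the integers [i - dl, i + dl] and clamped to the lattice
#' range, so the offspring always satisfies the chromosome invariants.
#'
#' @param parent length-8 chromosome.
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @param cfg an \code{ECConfig} (offsets, dl, lattice).
#' @return a length-8 chromosome.
#' @export
mutateChromosome <- function(parent, roiA, roiB, cfg) {
  ctxA <- .roiContext(roiA, cfg@lMin, cfg@lStep)
  ctxB <- .roiContext(roiB, cfg@lMin, cfg@lStep)
  .mutateCtx(parent, ctxA, ctxB, cfg)
}

.mutateCtx <- function(parent, ctxA, ctxB, cfg) {
  off <- cfg@offsetMm
  child <- parent
  child[1:3] <- pmin(pmax(parent[1:3] +
    stats::runif(3, -off[1:3], off[1:3]), ctxA$lo), ctxA$hi)
  child[5:7] <- pmin(pmax(parent[5:7] +
    stats::runif(3, -off[4:6], off[4:6]), ctxB$lo), ctxB$hi)
  child[4] <- .mutLattice(parent[4], cfg@dl[1], ctxA$nL)
  child[8] <- .mutLattice(parent[8], cfg@dl[2], ctxB$nL)
  child
}

# Uniform integer draw on [i - dl, i + dl] clamped to [0, nL - 1].
.mutLattice <- function(i, dl, nL) {
  lo <- max(0, i - dl); hi <- min(nL - 1, i + dl)
  if (hi <= lo) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' Population-elitist selection
#'
#' Parents and offspring are pooled and the \code{n} highest-fitness
#' chromosomes kept; ties at the cutoff are broken by earlier pool
#' position (parents come before offspring and the sort is stable).
#'
#' @param fitness numeric fitness of the pooled chromosomes, parents
#'   first.
#' @param n number to keep.
#' @return integer indices into the pool, in descending fitness order.
#' @export
selectPopulationElitist <- function(fitness, n) {
  order(-fitness, seq_along(fitness))[seq_len(n)]
}

# Evaluate one chromosome against the working matrices, memoizing BFS
# growth per (root, L) and caching the decoded-pair statistics.
.evalChromosome <- function(ch, ctxA, ctxB, M1, M2, cache) {
  rootA <- .decodeRootCtx(ch[1:3], ctxA)
  rootB <- .decodeRootCtx(ch[5:7], ctxB)
  LA <- ctxA$lVals[ch[4] + 1]
  LB <- ctxB$lVals[ch[8] + 1]
  kA <- paste0(rootA, ".", LA)
  kB <- paste0(rootB, ".", LB)
  mA <- cache$A[[kA]]
  if (is.null(mA)) cache$A[[kA]] <- mA <- .growBFSCtx(rootA, ctxA, LA)
  mB <- cache$B[[kB]]
  if (is.null(mB)) cache$B[[kB]] <- mB <- .growBFSCtx(rootB, ctxB, LB)
  sig <- paste0(paste(mA, collapse = ","), "|", paste(mB, collapse = ","))
  st <- cache$S[[sig]]
  if (is.null(st)) {
    NC1 <- sum(M1[mA, mB])
    NC2 <- sum(M2[mA, mB])
    TC <- length(mA) * length(mB)
    f <- fitnessZscore(NC1, NC2, TC)
    st <- list(rootA = rootA, rootB = rootB, mA = mA, mB = mB,
               NC1 = NC1, NC2 = NC2, TC = TC, sig = sig, fit = f)
    cache$S[[sig]] <- st
  }
  st
}

# Fresh per-level caches; the decoded-pair statistics cache (S) depends on
# the working matrices and must be dropped whenever edges are blocked,
# while the growth caches (A, B) are pure geometry and persist.
.levelCache <- function(geo) {
  e <- new.env(parent = emptyenv())
  e$A <- geo$A; e$B <- geo$B
  e$S <- new.env(parent = emptyenv())
  e
}

#' Run one level of the evolutionary search
#'
#' Initializes \code{populationSize} chromosomes uniformly over their
#' ranges, then iterates mutation, fitness evaluation (decode, count
#' edges, binomial z-score) and population-elitist selection until either
#' all chromosomes decode to the same voxel-set pair (complete
#' convergence) or the best-ever fitness has not improved by more than
#' 1e-12 for \code{stallGenerations} generations. Consumes the current
#' RNG stream; seed it (or use \code{detectAllSRPs}) for reproducibility.
#'
#' @param M1,M2 session-1/2 \code{BinaryConnectivityMatrix} or plain 0/1
#'   matrices.
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @param cfg an \code{ECConfig}.
#' @return list with \code{srp} (best-ever \code{SubRegionalPair} with
#'   full bookkeeping), \code{generations}, \code{trace} (best-ever
#'   fitness per generation).
#' @export
runECLevel <- function(M1, M2, roiA, roiB, cfg = ECConfig()) {
  if (is(M1, "BinaryConnectivityMatrix")) M1 <- connMatrix(M1)
  if (is(M2, "BinaryConnectivityMatrix")) M2 <- connMatrix(M2)
  ctxA <- .roiContext(roiA, cfg@lMin, cfg@lStep)
  ctxB <- .roiContext(roiB, cfg@lMin, cfg@lStep)
  geo <- list(A = new.env(parent = emptyenv()),
              B = new.env(parent = emptyenv()))
  .runLevel(M1, M2, ctxA, ctxB, cfg, geo)
}

.runLevel <- function(M1, M2, ctxA, ctxB, cfg, geo) {
  cache <- .levelCache(geo)
  npop <- cfg@populationSize
  pop <- lapply(seq_len(npop), function(i) .randomChromosome(ctxA, ctxB))
  evals <- lapply(pop, .evalChromosome, ctxA, ctxB, M1, M2, cache)
  best <- NULL; bestFit <- -Inf
  refresh <- function(evs) {
    fits <- vapply(evs, function(e) e$fit$fitness, numeric(1))
    i <- which.max(fits)
    if (fits[i] > bestFit + 1e-12) {
      bestFit <<- fits[i]; best <<- evs[[i]]
      TRUE
    } else FALSE
  }
  refresh(evals)
  trace <- bestFit
  stall <- 0L; gen <- 0L
  repeat {
    offspring <- unlist(lapply(pop, function(p)
      lapply(seq_len(cfg@offspringPerParent), function(o)
        .mutateCtx(p, ctxA, ctxB, cfg))), recursive = FALSE)
    evalsOff <- lapply(offspring, .evalChromosome, ctxA, ctxB, M1, M2,
                       cache)
    pool <- c(pop, offspring)
    poolEvals <- c(evals, evalsOff)
    fits <- vapply(poolEvals, function(e) e$fit$fitness, numeric(1))
    keep <- selectPopulationElitist(fits, npop)
    pop <- pool[keep]
    evals <- poolEvals[keep]
    gen <- gen + 1L
    improved <- refresh(evals)
    trace <- c(trace, bestFit)
    stall <- if (improved) 0L else stall + 1L
    sigs <- vapply(evals, function(e) e$sig, character(1))
    if (all(sigs == sigs[1])) break
    if (stall >= cfg@stallGenerations) break
  }
  srp <- .newSRP(best$rootA, best$rootB, best$mA, best$mB)
  srp@NC1 <- best$NC1; srp@NC2 <- best$NC2
  srp@EC2 <- best$fit$EC2; srp@SD <- best$fit$SD
  srp@Z <- best$fit$Z; srp@fitness <- best$fit$fitness
  srp@sign <- best$fit$sign
  srp@pRaw <- 2 * stats::pnorm(-abs(srp@Z))
  list(srp = srp, generations = gen, trace = trace)
}

#' Bonferroni correction over a set of detected pairs
#'
#' Each pair's raw p-value is the two-sided standard-normal tail
#' probability of |Z|; the corrected value is min(1, m * pRaw) with m the
#' number of pairs recorded in this run. Pairs with corrected p below
#' \code{alpha} survive.
#'
#' @param srpList list of \code{SubRegionalPair}s with Z set.
#' @param alpha significance level (default 0.05).
#' @return list with \code{survivors} and \code{all} (every input pair
#'   with pRaw/pCorrected filled in).
#' @export
bonferroniFilter <- function(srpList, alpha = 0.05) {
  m <- length(srpList)
  all <- lapply(srpList, function(s) {
    s@pRaw <- 2 * stats::pnorm(-abs(s@Z))
    s@pCorrected <- min(1, m * s@pRaw)
    s
  })
  keep <- vapply(all, function(s) s@pCorrected < alpha, logical(1))
  list(survivors = all[keep], all = all)
}

#' Detect all significantly plastic sub-regional pairs
#'
#' Recursive search with edge blocking: run one evolutionary level; if the
#' best fitness is below \code{zStop}, stop. Otherwise record the pair,
#' zero its member cells in working copies of both matrices (so later
#' levels find edge-disjoint pairs) and recurse. After the loop, apply
#' Bonferroni correction across all recorded pairs and keep the survivors.
#' Fully deterministic for a fixed \code{cfg@seed}.
#'
#' @param M1,M2 session-1/2 \code{BinaryConnectivityMatrix} or 0/1
#'   matrices.
#' @param roiA,roiB the two \code{ROIDefinition}s.
#' @param cfg an \code{ECConfig}.
#' @return An \code{ECResult}.
#' @export
detectAllSRPs <- function(M1, M2, roiA, roiB, cfg = ECConfig()) {
  if (is(M1, "BinaryConnectivityMatrix")) M1 <- connMatrix(M1)
  if (is(M2, "BinaryConnectivityMatrix")) M2 <- connMatrix(M2)
  stopifnot(identical(dim(M1), dim(M2)),
            nrow(M1) == roiSize(roiA), ncol(M1) == roiSize(roiB))
  set.seed(cfg@seed)
  ctxA <- .roiContext(roiA, cfg@lMin, cfg@lStep)
  ctxB <- .roiContext(roiB, cfg@lMin, cfg@lStep)
  geo <- list(A = new.env(parent = emptyenv()),
              B = new.env(parent = emptyenv()))
  M1w <- M1; M2w <- M2
  recorded <- list(); gens <- integer(0); traces <- list()
  level <- 1L
  repeat {
    res <- .runLevel(M1w, M2w, ctxA, ctxB, cfg, geo)
    gens <- c(gens, res$generations)
    traces <- c(traces, list(res$trace))
    if (res$srp@fitness < cfg@zStop) break
    res$srp@level <- level
    recorded <- c(recorded, list(res$srp))
    mA <- res$srp@membersA; mB <- res$srp@membersB
    M1w[mA, mB] <- 0
    M2w[mA, mB] <- 0
    if (level >= cfg@maxRecursion) {
      warning("maximum recursion depth reached; stopping early")
      break
    }
    level <- level + 1L
  }
  bf <- bonferroniFilter(recorded, cfg@alpha)
  new("ECResult", srps = bf$survivors, detected = bf$all,
      generationsRun = gens, bestFitnessTrace = traces,
      seed = cfg@seed, config = cfg, dims = dim(M1))
}
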
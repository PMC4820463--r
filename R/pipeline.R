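#' Full per-subject, per-ROI-pair analysis
#'
#' Orchestrates the pipeline: load the two-session inputs, build the two
#' binary connectivity matrices, run the recursive evolutionary search,
#' derive the plasticity estimate and both baselines, and write
#' \code{srps.tsv}, \code{summary.json}, \code{baseline.tsv} and
#' \code{manifest.json} (plus optional NIfTI label maps) to the output
#' directory. With \code{runs > 1}, one sub-directory per independent
#' seed is produced together with an aggregate \code{summary.json}
#' (mean/sd of the plasticity percentages) and a \code{compare.json} of
#' run-to-run reliability metrics.
#'
#' @param session1Path,session2Path,labelsPath input NIfTI paths.
#' @param roiALabel,roiBLabel integer ROI labels.
#' @param outDir output directory (created if needed).
#' @param cfg an \code{ECConfig}; its seed seeds run r as
#'   \code{seed + r - 1}.
#' @param q FDR level for the connectivity matrices (default 0.05).
#' @param runs number of independent searches (default 1).
#' @param writeMaps also write per-run SRP label maps as NIfTI.
#' @return \code{outDir}, invisibly.
#' @export
runSubject <- function(session1Path, session2Path, labelsPath,
                       roiALabel, roiBLabel, outDir,
                       cfg = ECConfig(), q = 0.05, runs = 1L,
                       writeMaps = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  out <- tryCatch({
    inp <- loadInputs(session1Path, session2Path, labelsPath,
                      roiALabel, roiBLabel)
    stage <- "connectivity"
    M1 <- buildBinaryMatrix(inp$tsA1, inp$tsB1, q)
    M2 <- buildBinaryMatrix(inp$tsA2, inp$tsB2, q)
    stage <- "search"
    results <- lapply(seq_len(runs), function(r) {
      cfgR <- cfg
      cfgR@seed <- cfg@seed + r - 1L
      res <- detectAllSRPs(M1, M2, inp$roiA, inp$roiB, cfgR)
      dir <- if (runs > 1) file.path(outDir, sprintf("run%02d", r))
             else outDir
      dir.create(dir, showWarnings = FALSE)
      .writeRunOutputs(res, inp, M1, M2, dir, q)
      if (writeMaps)
        writeSRPLabelMap(res, inp$roiA, inp$roiB,
                         file.path(dir, "srp_labels.nii.gz"))
      res
    })
    stage <- "aggregate"
    if (runs > 1) {
      est <- lapply(results, estimatePlasticity,
                    roiSize(inp$roiA), roiSize(inp$roiB))
      pos <- vapply(est, pctPositive, numeric(1))
      neg <- vapply(est, pctNegative, numeric(1))
      jsonlite::write_json(list(
        runs = runs,
        pctPositiveMean = mean(pos), pctPositiveSd = stats::sd(pos),
        pctNegativeMean = mean(neg), pctNegativeSd = stats::sd(neg)),
        file.path(outDir, "summary.json"), auto_unbox = TRUE,
        digits = NA)
      jsonlite::write_json(compareRuns(results),
                           file.path(outDir, "compare.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    .writeManifest(outDir, cfg, q, runs, ok = TRUE,
                   paths = c(session1Path, session2Path, labelsPath))
    invisible(outDir)
  }, error = function(e) {
    .writeManifest(outDir, cfg, q, runs, ok = FALSE, stage = stage,
                   message = conditionMessage(e))
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

.srpTable <- function(res, roiA, roiB) {
  rows <- lapply(srps(res), function(s) {
    vA <- roiVoxels(roiA)[membersA(s), , drop = FALSE]
    vB <- roiVoxels(roiB)[membersB(s), , drop = FALSE]
    fmt <- function(v) paste(apply(v, 1, paste, collapse = ","),
                             collapse = ";")
    data.frame(level = s@level, sign = s@sign, NC1 = s@NC1, NC2 = s@NC2,
               TC = s@TC, Z = s@Z, p_raw = s@pRaw,
               p_corrected = s@pCorrected,
               root_a = paste(roiVoxels(roiA)[s@rootA, ], collapse = ","),
               root_b = paste(roiVoxels(roiB)[s@rootB, ], collapse = ","),
               voxels_a = fmt(vA), voxels_b = fmt(vB))
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(level = integer(0), sign = integer(0),
                  NC1 = numeric(0), NC2 = numeric(0), TC = numeric(0),
                  Z = numeric(0), p_raw = numeric(0),
                  p_corrected = numeric(0), root_a = character(0),
                  root_b = character(0), voxels_a = character(0),
                  voxels_b = character(0))
}

.writeRunOutputs <- function(res, inp, M1, M2, dir, q) {
  utils::write.table(.srpTable(res, inp$roiA, inp$roiB),
                     file.path(dir, "srps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  est <- estimatePlasticity(res, roiSize(inp$roiA), roiSize(inp$roiB))
  jsonlite::write_json(list(
    seed = res@seed, q = q,
    nDetected = length(detectedPairs(res)),
    nSurviving = length(srps(res)),
    pctPositive = pctPositive(est), pctNegative = pctNegative(est),
    gl1 = gl1(est), totalPossible = est@totalPossible),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  avg1 <- averagingConnectivity(inp$tsA1, inp$tsB1)
  avg2 <- averagingConnectivity(inp$tsA2, inp$tsB2)
  ecc <- edgeCountChange(M1, M2)
  utils::write.table(data.frame(
    method = c("averaging", "edge_count"),
    session1_stat = c(avg1$r, ecc$count1),
    session2_stat = c(avg2$r, ecc$count2),
    gl2 = c(NA, ecc$gl2)),
    file.path(dir, "baseline.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
}

.writeManifest <- function(dir, cfg, q, runs, ok, stage = NA,
                           message = NA, paths = character(0)) {
  jsonlite::write_json(list(
    package = "plastEC",
    version = as.character(utils::packageVersion("plastEC")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    ok = ok, failed_stage = stage, message = message,
    inputs = as.list(paths),
    q = q, runs = runs,
    config = list(populationSize = cfg@populationSize,
                  offsetMm = cfg@offsetMm, dl = cfg@dl,
                  offspringPerParent = cfg@offspringPerParent,
                  stallGenerations = cfg@stallGenerations,
                  zStop = cfg@zStop, alpha = cfg@alpha,
                  maxRecursion = cfg@maxRecursion, lMin = cfg@lMin,
                  lStep = cfg@lStep, seed = cfg@seed)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a synthetic two-session dataset to disk
#'
#' \code{preset = "timeseries"} writes two 4-D BOLD NIfTI volumes, a label
#' volume (labels 1 and 2) and \code{truth.json}; the planted block gains
#' coupling between sessions, so the full pipeline should recover a
#' positively plastic pair. \code{preset = "matrix"} writes the two
#' planted binary matrices as TSV plus the truth file.
#'
#' @param preset \code{"timeseries"} or \code{"matrix"}.
#' @param outDir output directory.
#' @param seed RNG seed.
#' @param shape grid dimensions.
#' @param roiSizes the two ROI sizes.
#' @param blockSizes planted block sizes within the ROIs.
#' @param T time points per session (timeseries preset).
#' @return \code{outDir}, invisibly.
#' @export
simulateDataset <- function(preset = c("timeseries", "matrix"), outDir,
                            seed = 1L, shape = c(8, 8, 8),
                            roiSizes = c(40, 40), blockSizes = c(12, 12),
                            T = 145L) {
  preset <- match.arg(preset)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  geo <- makeGeometry(shape, roiSizes)
  truthFile <- file.path(outDir, "truth.json")
  if (preset == "matrix") {
    block <- plantBlock(geo$roiA, geo$roiB, blockSizes[1], blockSizes[2],
                        d1 = 0.05, d2 = 0.9)
    truth <- plantedTruth(list(block), background = 0.02)
    ds <- makeMatrixDataset(truth, geo$roiA, geo$roiB)
    utils::write.table(connMatrix(ds$M1), file.path(outDir, "M1.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(connMatrix(ds$M2), file.path(outDir, "M2.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    block <- plantBlock(geo$roiA, geo$roiB, blockSizes[1], blockSizes[2],
                        c1 = 0, c2 = 1.5)
    truth <- plantedTruth(list(block))
    ds <- makeTimeseriesDataset(truth, geo$roiA, geo$roiB, T)
    vol <- function(tsA, tsB) {
      v <- array(stats::rnorm(prod(shape) * T), dim = c(shape, T))
      flat <- matrix(v, prod(shape), T)
      flat[.linearIndex(roiVoxels(geo$roiA), shape) + 1, ] <- tsData(tsA)
      flat[.linearIndex(roiVoxels(geo$roiB), shape) + 1, ] <- tsData(tsB)
      array(flat, dim = c(shape, T))
    }
    img1 <- RNifti::asNifti(vol(ds$tsA1, ds$tsB1))
    img2 <- RNifti::asNifti(vol(ds$tsA2, ds$tsB2))
    aff <- structure(gridAffine(geo$grid), code = 2L)
    for (nm in c("img1", "img2")) {
      img <- get(nm)
      RNifti::pixdim(img) <- c(voxelSize(geo$grid), 1)
      RNifti::qform(img) <- aff
      RNifti::sform(img) <- aff
      assign(nm, img)
    }
    RNifti::writeNifti(img1, file.path(outDir, "session1.nii.gz"))
    RNifti::writeNifti(img2, file.path(outDir, "session2.nii.gz"))
    lab <- array(0L, dim = shape)
    lab[roiVoxels(geo$roiA) + 1L] <- 1L
    lab[roiVoxels(geo$roiB) + 1L] <- 2L
    writeVolume(lab, geo$grid, file.path(outDir, "labels.nii.gz"))
  }
  jsonlite::write_json(list(
    preset = preset, seed = seed, shape = shape, roiSizes = roiSizes,
    background = truth$background,
    blocks = lapply(truth$blocks, function(b)
      b[intersect(names(b), c("membersA", "membersB", "d1", "d2",
                              "c1", "c2"))]),
    roiA = apply(roiVoxels(geo$roiA), 1, paste, collapse = ","),
    roiB = apply(roiVoxels(geo$roiB), 1, paste, collapse = ",")),
    truthFile, auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Compare result directories from independent runs
#'
#' Reads the \code{srps.tsv} of each directory and recomputes the
#' reliability metrics on the recorded voxel sets.
#'
#' @param dirs two or more run directories written by \code{runSubject}.
#' @param nA,nB the two ROI sizes (needed to rebuild the labelings).
#' @param grid the \code{VoxelGrid}; together with \code{roiA},
#'   \code{roiB} used to map voxel coordinates back to ROI indices.
#' @param roiA,roiB the \code{ROIDefinition}s of the analysis.
#' @return the \code{compareRuns}-style metric list.
#' @export
compareRunDirs <- function(dirs, roiA, roiB) {
  keyA <- .linearIndex(roiVoxels(roiA), gridShape(roiGrid(roiA)))
  keyB <- .linearIndex(roiVoxels(roiB), gridShape(roiGrid(roiB)))
  parse <- function(dir) {
    tab <- utils::read.delim(file.path(dir, "srps.tsv"),
                             stringsAsFactors = FALSE)
    lapply(seq_len(nrow(tab)), function(r) {
      toIdx <- function(txt, keys, sh) {
        v <- do.call(rbind, lapply(strsplit(txt, ";")[[1]], function(s)
          as.integer(strsplit(s, ",")[[1]])))
        match(.linearIndex(v, sh), keys)
      }
      sh <- gridShape(roiGrid(roiA))
      mA <- toIdx(tab$voxels_a[r], keyA, sh)
      mB <- toIdx(tab$voxels_b[r], keyB, sh)
      s <- .newSRP(mA[1], mB[1], mA, mB, level = tab$level[r])
      s@NC1 <- tab$NC1[r]; s@NC2 <- tab$NC2[r]
      s@Z <- tab$Z[r]; s@pCorrected = tab$p_corrected[r]
      s
    })
  }
  runs <- lapply(dirs, parse)
  nA <- roiSize(roiA); nB <- roiSize(roiB)
  pairs <- utils::combn(length(runs), 2)
  dice <- apply(pairs, 2, function(p)
    diceOverlapRuns(runs[[p[1]]], runs[[p[2]]], nA))
  ari <- apply(pairs, 2, function(p)
    ariVoxelPairLabelings(runs[[p[1]]], runs[[p[2]]], nA, nB))
  list(diceMean = mean(dice, na.rm = TRUE), ariMean = mean(ari),
       ariSd = stats::sd(ari),
       consistencyPct = voxelPairConsistency(runs, nA, nB),
       nRunPairs = ncol(pairs))
}
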
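---
title: "Detecting plastic sub-regional pairs with an evolutionary search"
author: "plastEC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plastic sub-regional pairs with an evolutionary search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Longitudinal fMRI studies often ask whether the functional relationship
between two regions of interest (ROIs) changes between two scan sessions.
The conventional answer — correlate the ROI-averaged BOLD signals per
session and compare — throws away spatial structure: when only a small
sub-cluster of each ROI changes its coupling, or when one sub-cluster
gains connectivity while another loses it, the averaged signals can show
no change at all. plastEC implements a voxel-level alternative: it
searches for *sub-regional pairs* — one spatially 6-connected cluster of
voxels per ROI — whose number of significant voxel-wise connections
changes far more between sessions than chance allows.

## From BOLD series to binary connectivity matrices

For a ROI pair A-B and each session separately, every voxel of A is
correlated (Pearson) with every voxel of B. The two-sided p-value of each
correlation comes from the exact t transform with `T - 2` degrees of
freedom, where `T` is the number of retained volumes (145 in a typical
5-minute acquisition after discarding the first five). The full family of
`|A| x |B|` p-values is screened by the Benjamini–Hochberg step-up
procedure at `q = 0.05`; cells that fail FDR or whose correlation is not
positive are set to 0, the rest to 1. The result is one binary matrix per
session, `M1` and `M2`, whose row/column identity is fixed by the
deterministic raster order (ascending i, then j, then k) in which ROI
voxels are read from the label volume.

Choices made where the construction is underdetermined:

* FDR is applied per matrix (per subject, session and ROI pair), i.e.
  over the `|A| x |B|` tests — each session's matrix is an independent
  construction.
* "FDR" is read as Benjamini–Hochberg, the standard interpretation of an
  FDR test at a fixed level. The step-up rule is implemented literally on
  the p scale (find the largest k with `p(k) <= k q / m`, keep
  `p <= p(k)`); it coincides with thresholding `p.adjust(..., "BH")` at
  `q` except at exact floating-point boundary ties.
* Zero-variance voxels produce no edges instead of aborting, with a
  warning, so partially degenerate synthetic inputs still run.
* Only positive correlations are used; a sign policy for negative-edge
  analyses is deliberately out of scope.

## Chromosome encoding and decoding

A candidate solution is encoded indirectly by eight genes
`(X1, Y1, Z1, L1, X2, Y2, Z2, L2)`. The spatial genes are mm coordinates
constrained to the axis-aligned bounding cuboid of each ROI's voxel
centers (boundary inclusive); the size genes live on a quantization
lattice `{lMin, lMin + lStep, ...}` capped at the ROI size, and are
stored as 0-based lattice indices so that mutation operates in lattice
steps. Decoding proceeds in two deterministic steps per ROI:

1. **Root selection.** The ROI voxel whose center is nearest (Euclidean
   mm distance) to the point `(X, Y, Z)` becomes the root; ties within
   1e-9 are broken by the smallest z, then y, then x center coordinate.
2. **BFS growth.** A FIFO breadth-first search over 6-neighbor adjacency
   restricted to ROI voxels adds the first `L` voxels enqueued; at every
   frontier expansion the unvisited neighbors are enqueued in ascending
   (z, y, x) order. Applying the priority at every expansion (not only in
   the final partial layer) makes the grown shape fully deterministic;
   the shape itself carries little meaning, only location and size do.
   If fewer than `L` voxels are reachable, the root's whole connected
   component is returned, so a disconnected ROI degrades gracefully
   instead of aborting.

The size gene is interpreted as the number of neighbors *added to* the
root: a sub-region holds `L + 1` voxels (capped by the component size).
Decoding is a pure function of (chromosome, ROIs), and two chromosomes
whose points share a nearest voxel decode identically — the search space
is effectively (root voxel, L) pairs.

## The objective and the search

For a decoded pair, let `NC1` and `NC2` be the edge counts over its
member submatrix in `M1` and `M2`, and `TC = |subA| x |subB|` the total
possible connections (always the full product, also after edge blocking —
blocked cells simply contribute zero to both counts). Treating the
session-1 rate `P1 = NC1/TC` as a binomial null for session 2:

    EC2 = P1 * TC          (expected session-2 count, = NC1)
    SD  = sqrt(TC * P1 * (1 - P1))
    Z   = (NC2 - EC2) / SD
    fitness = |Z|

When `P1` is 0 or 1 the binomial SD vanishes; `P1` is clamped to
`[0.5/TC, 1 - 0.5/TC]` (a continuity correction) before the formulas
apply, and if additionally `NC2 = NC1` the fitness is defined as 0. This
preserves "no change, zero fitness" exactly while letting a total gain
from an empty baseline (or total loss from a full one) score very high,
which is the intended behavior of the objective. The direction of
plasticity is the sign of `NC2 - NC1`, assigned post hoc.

One search level runs a population of chromosomes (default 400) through
uniform initialization over the cuboids and lattices, a single-parent
mutation operator (each spatial gene drawn uniformly within ±6 mm and
clamped to the cuboid; each size-gene index within ±4 lattice steps and
clamped), fitness evaluation, and population-elitist selection: parents
and offspring pooled, top 50% kept, ties at the cutoff resolved stably in
favor of earlier pool position. The level stops on complete convergence —
tested on decoded voxel sets, since distinct genes can decode identically
— or when the best-ever fitness has not improved by more than 1e-12 for
100 generations (both configurable). With one offspring per parent the
pool is exactly twice the population, which is why "top 50%" keeps the
population size constant; the offspring count is configurable.

The recursion wraps levels: if the best pair of a level has
`|Z| >= zStop` (default 1) it is recorded and all its member cells are
zeroed in working copies of both matrices, so subsequent levels must find
edge-disjoint pairs; the loop ends at the first level whose best falls
below `zStop`. Finally, Bonferroni correction is applied across the m
pairs recorded in this run (not across subjects or ROI pairs — the
family is the set of binomial tests this search performed):
`p_corrected = min(1, m * p_raw)` with `p_raw` the two-sided normal tail
of `|Z|`; pairs with `p_corrected < 0.05` survive. One RNG stream drives
the whole run, seeded from the configuration, with recursion levels
consuming it sequentially — a fixed seed reproduces the result
bit-identically.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `populationSize` | 400 | chromosomes | search breadth per level |
| `offsetMm` | 6 | mm | spatial mutation half-range (≈ 2 voxels at 3 mm) |
| `dl` | 4 | lattice steps | size-gene mutation half-range |
| `offspringPerParent` | 1 | – | pool = 2N, matching top-50% selection |
| `stallGenerations` | 100 | generations | stall stopping criterion |
| `zStop` | 1 | z-score | recursion stop threshold |
| `alpha` | 0.05 | – | Bonferroni-corrected significance level |
| `lMin`, `lStep` | 64, 5 | voxels | size lattice origin and step |
| `q` | 0.05 | – | FDR level of the matrix construction |

The `dl` offsets are measured in lattice steps rather than raw voxels:
at `lStep = 5`, ±4 raw voxels would be smaller than one lattice step and
the size gene could never move, so ±4 steps (±20 voxels) is the reading
that keeps the gene mutable. The 64-voxel lattice origin reflects
whole-brain ROIs of hundreds to thousands of voxels; the toy problems in
the test-suite use `lMin = 1, lStep = 1` so that few-voxel ROIs remain
searchable. Anisotropic grids are accepted; the mm mutation offsets are
not rescaled per axis, matching their definition in mm.

## The synthetic generator

Two entry points share a common planted-truth contract so the search
core can be tested in isolation from the correlation/FDR stage:

* **Matrix level.** Every cell has a session-1 and session-2 Bernoulli
  density — a background density everywhere, block-specific densities
  inside each planted pair of 6-connected sub-regions (grown by the same
  BFS the decoder uses, so planted shapes are decodable). Cells whose two
  densities are equal are drawn once and shared between sessions:
  unchanged functional structure is stable across sessions, and a
  dataset with no planted change has `M1` identical to `M2`. Cells with
  differing densities are drawn independently per session.
* **Time-series level.** Each planted block has one latent standard
  normal signal per session added to the member voxels of both ROIs with
  a session-specific coupling amplitude, over i.i.d. unit-variance
  Gaussian noise. A coupling `c` yields pairwise block correlations near
  `c^2 / (c^2 + 1)`, so raising the session-2 coupling plants positive
  plasticity through the full pipeline.

What the generator does *not* emulate: hemodynamic autocorrelation,
physiological noise, motion artifacts, spatial smoothing, or session
differences in global signal amplitude. Passing the recovery tests shows
the machinery is correct under its own model, not that effect sizes on
real data will match.

One empirical caveat the generator exposes: with unchanged coupling in
both sessions, the FDR-binarized matrices still differ slightly — BH
admits approximately a fraction `q` of false edges among its discoveries,
and these fall on different cells in the two (independently noisy)
sessions. The search can occasionally assemble a few such cells into a
small pair that survives correction. Spurious plasticity of this kind is
an order of magnitude below planted effects at the scales tested (< 2%
of possible edges vs ~15% planted), and mirrors the nonzero plasticity
the method reports on stable healthy brains; it is a property of
FDR-binarized edge counting, not of the search.

## Baselines and reliability metrics

The averaging baseline correlates the ROI-mean series per session and
Fisher z-transforms the result; the simple voxel-level baseline counts
1-cells per session, with `gl2` its absolute net change (the only
quantity derivable from totals alone — which is precisely the baseline's
weakness, since cancelling gains and losses drive `gl2` to zero while
the sub-regional estimate `gl1` = gains + losses does not cancel).
Group-level reporting utilities (paired t on Fisher-z values, paired
Wilcoxon on counts, rank-sum with Shapiro–Wilk screens) are thin wrappers
over the standard tests.

Between-run reliability is quantified three ways: the mean maximal
Sorenson-dice overlap between the detected pairs of two runs (each pair's
voxel set is the ROI-tagged union of its two sub-regions, so a voxel of
ROI-A never collides with the same coordinate in ROI-B); the adjusted
Rand index between voxel-pair labelings (label 0 for cells in no
surviving pair, else the pair index — well defined because blocking makes
supports disjoint); and voxel-pair consistency, the mean over unordered
run pairs of the percentage of cells with equal binary membership.
Pairwise (rather than against-majority) agreement is used for
consistency, matching the run-pair structure of the other two metrics.
The ARI is computed by `mclust::adjustedRandIndex` and pinned in tests to
hand-computed pair-counting values.

## Numerical choices and degenerate inputs

* Correlations are clamped to [-1, 1] before the t transform; `|r| = 1`
  maps to p = 0.
* Stall detection uses strict improvement of the best-ever fitness with
  tolerance 1e-12.
* Selection ties are broken stably (parents before offspring), making
  every level deterministic given the RNG stream.
* Root-selection ties use a 1e-9 distance tolerance and (z, y, x) order.
* Empty ROIs, grid mismatches beyond 1e-6, out-of-bounds voxels and
  non-finite series are hard errors; zero-variance voxels and
  constant-mean series are flagged degenerate and carried as "no edge".

## Problem sizes in the test-suite

The packaged tests run the search on ROIs of 25–40 voxels with
populations of 40–150 and stall windows of 10–30 generations, planted
blocks covering ≥ 20% of the matrix, and 3–10 seeds per stochastic
property; exhaustive-enumeration cross-checks use ROI pairs small enough
(≤ 6 voxels) to enumerate every decodable pair. These sizes were chosen
as the smallest at which the planted structure is unambiguous; the
defaults (population 400, stall 100) remain the recommended operating
point for real whole-ROI analyses.

## Known limitations

* Binarization discards correlation magnitudes by design; weighted
  variants are out of scope.
* The recursion's `zStop = 1` is a heuristic floor: a level that
  converges poorly can end the recursion early. Large populations (or
  multiple independent runs, which the multi-run driver and reliability
  metrics support directly) are the recommended mitigations.
* Bonferroni across recorded pairs is conservative and its family size
  depends on how many levels the recursion ran.
* The method is agnostic to ROI provenance but assumes both sessions are
  already preprocessed, normalized to a common grid, and labeled by the
  user; no preprocessing is performed.
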
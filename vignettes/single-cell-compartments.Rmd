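---
title: "Calling single-cell A/B compartments by semidefinite max-cut"
author: "scMaxCut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling single-cell A/B compartments by semidefinite max-cut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMaxCut)
```

## The problem

Bulk Hi-C partitions the genome into two large-scale chromatin classes
— the open, transcriptionally active A compartment and the condensed B
compartment — by the sign of the first principal component (PC1) of
the contact matrix. That annotation is an average over millions of
cells. Chromatin-tracing imaging (DNA MERFISH, seqFISH+) and 3D genome
structure models instead give the actual 3D fold of single chromosomes
in single cells, where compartments vary from cell to cell. This
package annotates A/B compartments *per cell, per chromosome copy*
directly from such 3D structures, with no population averaging in the
call itself.

The input is a set of chromatin traces: for one chromosome copy in one
cell, the 3D coordinates (nm) of an ordered panel of genomic bins,
plus per-bin distances to the nearest nuclear speckle (or imaged
speckle-marker intensities, from which pseudo-distances are derived).
Nuclear speckles are interchromatin granules enriched in splicing
factors; proximity to them marks active chromatin, which is what makes
the A/B orientation of a geometric bipartition identifiable in a
single cell.

## From a structure to a graph

Each trace becomes an undirected weighted graph with one node per bin.
Two assumptions drive the edge weights:

1. loci of the same compartment are spatially closer than expected
   from their genomic separation alone (at short range the expected
   distance scales as the square root of the genomic separation), and
2. loci of the same compartment have similar distances to nuclear
   speckles.

For loci $i<j$ with coordinates $x_i$, panel indices $g_i$, and
per-trace z-scored speckle distances $z_i$,

$$w_{ij} \;=\; |z_i - z_j|\;\frac{\lVert x_i - x_j\rVert_2}{\sqrt{|g_i-g_j|}},$$

so *large* weights join loci that look like they belong to *different*
compartments (dissimilar speckle affinity, farther apart than their
genomic separation predicts). Edges with
$\lVert x_i-x_j\rVert_2 > 16\,R_{bead}$ are removed — compartments are
determined by local structural relationships — and the surviving
weights are divided by their maximum so that $w'_{ij}\in[0,1]$. The
two compartments are then the two sides of the **maximum cut** of this
graph: the bipartition that places as much edge weight as possible
*between* the groups, i.e. keeps similar loci together.

Choices worth making explicit:

* **z-scores are computed per trace**, not across the population:
  imaging batches differ cell to cell, and the weights describe a
  single structure. A configuration switch is not offered because
  population-level standardization would leak ensemble information
  into a single-cell call.
* **Genomic separation is the panel bin index** by default. The
  weight formula is invariant to a uniform rescaling of $g$ (a common
  factor divides all weights and the max-normalization removes it),
  so bin units need not be base pairs; `gapMode = "bp"` uses
  `bin_start/resolution` for panels with heterogeneous spacing.
* **Min–max normalization runs over kept edges only**; pruned pairs
  are exact zeros and cannot be the maximum.
* **Ties in the z-scores zero an edge** even for distant pairs; the
  formula is kept verbatim (`epsilonZ = 0`). Degenerate inputs with
  constant speckle distance yield an all-zero graph and a clear error
  rather than an arbitrary partition; `epsilonZ > 0` can rescue such
  synthetic corner cases.
* $R_{bead}$ defaults to 100 nm, the appropriate value for imaging
  data at MERFISH/seqFISH+ resolutions. For modeled or synthetic
  structures the bead radius is a property of the model and must be
  given explicitly (the synthetic runs below use 200 nm, a reasonable
  excluded-volume radius for a 200-kb bead in a 5-µm nucleus).

## The max-cut relaxation

Max-cut is NP-hard, so the package uses the Goemans–Williamson
semidefinite relaxation. With the graph Laplacian $L = E - W$ (degree
matrix $E$), the cut value of labels $s\in\{\pm1\}^n$ is
$\tfrac14 s^T L s$. Relaxing each label to a unit vector and writing
$A_{ij} = v_i^T v_j$ gives the SDP

$$\max_A \tfrac14\,\mathrm{tr}(L^T A)\quad\text{s.t. } \mathrm{diag}(A)=1,\; A \succeq 0 .$$

**Solver.** The package ships its own ADMM splitting solver for this
SDP (`solveSdp()`): alternately solve the linear subproblem under the
unit-diagonal constraint and project onto the positive semidefinite
cone (one symmetric eigendecomposition per iteration), with residual
balancing of the penalty parameter. Default tolerance is $10^{-6}$ on
the scaled residuals, with a single automatic retry at $10^{-4}$;
iteration cap 5000. Two post-processing steps make the output robust
to solver accuracy:

* the primal iterate is rescaled to an **exactly** unit diagonal (a
  PSD-preserving congruence), so the reported objective is a true
  lower bound on the relaxation optimum, and
* a **certified upper bound** is extracted from the dual: with
  $y_i = (LA)_{ii}/4$, shifting all $y_i$ by the most negative
  eigenvalue of $\mathrm{diag}(y) - L/4$ yields a feasible dual point
  whose value bounds the relaxation — and hence the true maximum cut —
  from above, regardless of how converged the primal is. Weak duality
  (`cut <= sdpBound`) therefore holds by certificate everywhere in the
  package, not approximately.

**Factorization.** Node vectors are recovered by a root-free LDL
factorization $A = U D U^T$ rather than Cholesky, because the solved
$A$ may have eigenvalues a hair below zero. Negative entries of $D$
are clamped to zero and $V' = U\sqrt{D'}$; the reconstruction error
$\lVert V'V'^T - A\rVert$ is of the order of the clamped mass, so a
nearly-PSD input gives nearly-exact vectors. Pivots below
$10^{-10}\max(1, \max_i A_{ii})$ are treated as zero to avoid
eliminating with an unstable tiny pivot.

**Rounding.** A random hyperplane with standard-normal direction $r$
labels node $i$ by $\mathrm{sign}(v_i'\cdot r)$ (zero dot products
break to $+1$ — a measure-zero event, resolved deterministically).
Draws repeat until the cut reaches $0.878\times$ the certified SDP
bound or a cap (default 1000) is hit, keeping the best cut seen. The
classical 0.878 guarantee is stated relative to the unknown optimum;
using the SDP bound, which is at least the optimum, makes the stopping
rule strictly more demanding. When the cap is reached the best cut is
returned with a warning, never an exception. Each call draws from a
seeded generator and records its seed; draws are sequential, so a
batched evaluation returns bitwise the same result as one-at-a-time
drawing.

## From a cut to compartments

The cut is anonymous; speckle biology orients it: the side with the
smaller mean speckle distance becomes A (`assignAB()`). On an exact
tie the side containing the first node is A — deterministic and
logged. A cut with an empty side is an error (the graph was
degenerate).

Per-cell binary profiles $c_k$ (1 = A) aggregate across $K$ cells
into:

* the **ensemble vector** $c^{ens} = \frac1K\sum_k c_k$,
* the **compartment frequency**
  $f_i = c^{ens}_i - [c^{ens}_i < 0.5]$, which is the signed fraction
  of cells in the majority compartment, so $|f_i| \ge 0.5$ always
  (note the boundary: $c^{ens}_i = 0.5$ maps to $+0.5$ because the
  indicator is strict),
* the **normalized frequency** $f^{norm}_i = c^{ens}_i - 0.5$, the
  quantity compared with external PC1 profiles, and
* the **variability**
  $\delta c_i = \sqrt{\frac1K\sum_k (c_{ki}-\bar c_i)^2}$, the
  population standard deviation, which for binary calls equals
  $\sqrt{c^{ens}_i(1-c^{ens}_i)}$ exactly — the test suite asserts
  this identity rather than re-deriving the number.

The frequency $f$ is deliberately implemented exactly as printed even
though its range excludes $(-0.5, 0.5)$; narrative statements about
frequencies "close to zero" refer to $f^{norm}$.

**Transcription analysis.** With per-cell per-gene nascent transcript
counts and two homolog traces per cell, `transcriptionRatio()` groups
cells per gene into A cells (gene's bin called A on both copies) and B
cells (B on both), after dropping the bottom 5% of cells by that
gene's count (guarding zero-inflation; the count dropped is
`floor(0.05 n)`, with ties broken by stable order). The ratio is
$\log_2(t_A/t_B)$ of the group mean counts; an empty group or zero
$t_B$ yields `NA`, never an imputed value. Cells lacking both homologs
are excluded.

## Structural features and compartmentalization scores

`radialPosition()` ($\lVert x\rVert/R_{nuc}$, default
$R_{nuc} = 5\,\mu m$; the nucleus centre defaults to the origin for
modeled structures — use the cell centroid for imaging data),
`radialVariability()` ($\log_2$ of a bin's across-cell spread against
the chromosome mean spread), `radiusOfGyration()` (5-bin sliding
window = 1 Mb at 200 kb; end windows shrink),
`interchromContacts()` (foreign beads within $R_{soft} = 1000$ nm) and
`speckleVariability()` describe the structures themselves. Population
standard deviations divide by $K$ throughout, matching the $\delta c$
convention.

Two scores evaluate *any* compartment annotation on a structure:

* **CCS** $s_c = n_{intra}/(n_{intra}+n_{inter})$, the fraction of
  spatial contacts (distance $\le 3R_{bead}$; 4 for MERFISH-resolution
  data) inside compartments — higher is better. Sequence-adjacent
  pairs count as contacts by default (`includeAdjacent = FALSE` to
  exclude); they are label-insensitive ballast either way.
* **DCS** $s_d = d_{intra}/(d_{intra}+d_{inter})$ on summed pairwise
  distances — lower is better. The sums follow the formula; a
  mean-based variant (`useMean = TRUE`) is offered because sums depend
  on group sizes.

Both return `NA` for degenerate inputs (no contacts, an empty
compartment, all points coincident) rather than a conventional value.

## Baseline callers

* `distancePca()` — the ensemble method adapted to imaging: mean
  pairwise distance matrix, normalized by a fitted power law
  $a\cdot gap^b$ (log–log OLS; a quadratic fit describes the same
  trend but OLS in log space is the stable standard), Pearson
  correlation matrix of its rows (the zero-separation diagonal is
  excluded pairwise), leading eigenvector, sign split. One annotation
  for all cells.
* `cgPhasing()` — genuinely single-cell: a locus's smoothed CG is the
  mean CG over all loci within 250 nm (itself included; an isolated
  locus keeps its own CG), called A when its $\log_2$ fold change
  against the same-cell mean is strictly positive (so a uniform track
  yields all-B — the boundary is documented, not hidden). The
  reference mean can be overridden with a population-wide value.
* `hicPca()` — PC1 of a user-supplied dense matrix, correlation
  transform first by default with the covariance-first order exposed,
  since ensemble pipelines differ.

PC1 sign is not identified by the eigendecomposition; all callers
orient by mean speckle distance (A = speckle-proximal), falling back
to CG content. `profileCorrelation()` compares profiles by Pearson r
over bins where both are defined and the prediction is non-zero.

## The synthetic generator

`simulatePopulation()` is a phenomenological two-attractor model, not
a polymer simulation. It reproduces exactly the two assumptions the
caller exploits — intra-compartment spatial proximity and A-speckle
proximity — and nothing else:

* labels: a two-state Markov chain along the bins
  (`switchProb = 0.1` default, i.e. 10-bin ≈ 2 Mb expected blocks at
  200 kb resolution, a realistic compartment block scale);
* geometry: per cell, each bead's *effective* label flips with
  probability `labelNoise` (cell-to-cell variability), then a
  sequential Gaussian random walk (`stepSd = 150` nm) is pulled a
  fraction `pull` toward its compartment's attractor; the attractors
  sit `separation = 2000` nm apart inside a `nucleusRadius = 5000` nm
  sphere and coordinates are clipped to it;
* speckles: `nSpeckles = 3` points at the A attractor with 200 nm
  placement jitter; the recorded speckle distance is the distance to
  the nearest speckle plus Gaussian measurement noise
  (`speckleNoiseSd = 100` nm, unclipped — it is measurement noise);
* transcripts: per gene (mapped to a bin), Poisson counts with mean
  `rateA = 10` when the bin is effectively A on all homologs,
  `rateB = 2` when B on all, and the midpoint otherwise.

All randomness derives from one master seed through per-cell
substreams, so runs are reproducible and the first $k$ cells of a
$K$-cell population equal a $k$-cell run.

What the generator does **not** emulate — and therefore what passing
tests do *not* establish about real data: polymer connectivity beyond
a first-order walk, TADs and loop extrusion, compartment
interdigitation at sub-attractor scale, chromosome territories,
realistic speckle number and geometry, imaging detection dropout
structure, and diploid homolog proximity. Results on real traces
depend on those properties; the synthetic runs validate the
algorithmic chain, not the biology.

## Validation setup and numerical choices

The shipped validation (test suite and `scripts/acceptance.R`) uses
problem sizes chosen to exercise the method honestly on one CPU:

* **Exact-oracle benchmark**: 50 random complete graphs with 8–12
  nodes and i.i.d. uniform(0,1) weights; the exact maximum cut comes
  from enumerating all $2^{n-1}$ bipartitions. Rounding runs the full
  500 draws (threshold ratio 1) so the best cut is comparable with the
  optimum; the production early stop at $0.878\times$bound would
  legitimately return earlier, lower cuts.
* **Planted-partition runs**: 60-bin chromosomes, $K = 200$ cells at
  the strong setting (pull 0.8, separation 2000 nm, label noise 0.05)
  and a $K = 100$ control at pull 0, where recovery must sit at
  chance.

Other numerical policies, collected: missing coordinates interpolate
linearly in bin index between flanking observed loci and copy the
nearest value at the ends (no extrapolation); traces with fewer than
two observed loci are rejected; loci with missing speckle values
interpolate per trace the same way. Distances are nanometres
internally, with µm converted on input. Genomic intervals are 0-based
half-open. Nonpositive speckle intensities floor to the smallest
positive observed intensity (with a warning) before the
$1/\sqrt{s}$ conversion. Disconnected graphs are allowed (the SDP and
rounding handle them); only degenerate all-zero graphs are errors. In
population runs every failure is caught per trace and recorded in the
diagnostics table, so one bad cell never aborts a run.

## Limitations

* The SDP scales as one dense eigendecomposition per ADMM iteration;
  chromosomes of several hundred bins are minutes per cell, so whole
  populations at that size benefit from the prune-induced sparsity
  and patience.
* A/B orientation needs speckle information (distances or
  intensities); without any, single-cell orientation is
  unidentifiable and calling stops with a configuration error.
* The two-compartment assumption is structural: subcompartments would
  require recursive cutting, which this package does not attempt.
* Homologs are treated as separate traces everywhere except the
  transcription grouping, which requires an explicit homolog column.

## A worked run

```{r run, eval = FALSE}
cfg <- syntheticConfig(nLoci = 40, nCells = 20, seed = 1)
sim <- simulatePopulation(cfg)
res <- callCompartments(sim$population, rBead = 200, seed = 1)
mean(truthAccuracy(res$profiles, sim$truth))
ens <- ensembleCompartments(res$profiles, tracePanel(sim$population))
profileCorrelation(ens@fNorm, sim$truth)
scores <- scoreCompartments(sim$population, res$profiles, rBead = 200)
summary(scores$ccs)
```
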
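# scMaxCut

A/B chromatin compartment calling for **single cells**, directly from
3D chromosome structures (chromatin-tracing imaging such as DNA
MERFISH / seqFISH+, or 3D genome structure models). Bulk Hi-C assigns
compartments from the sign of PC1 of the population-averaged contact
matrix; this package instead annotates each chromosome copy of each
cell on its own, so compartment variability across cells becomes an
observable rather than an artifact of averaging.

Intended users: groups analyzing chromatin-tracing or genome-structure
ensembles who want per-cell compartment annotations, population
compartment-frequency profiles comparable with Hi-C PC1, and
quantitative scores to compare annotation methods.

## Method

Each trace (one chromosome copy in one cell: bins with 3D coordinates
`x_i` in nm and speckle distances `SpD_i`) becomes a weighted graph.
With per-trace z-scores `z_i` of speckle distance and panel index
`g_i`, the weight of edge (i, j) is

    w_ij = |z_i - z_j| * ||x_i - x_j|| / sqrt(|g_i - g_j|)

pruned when `||x_i - x_j|| > 16 R_bead` and max-normalized into
[0, 1]. Large weights join loci that look like they belong to
different compartments, so the two compartments are the **maximum
cut** of this graph. The cut is approximated the Goemans–Williamson
way: solve the semidefinite relaxation

    max (1/4) tr(L A)   s.t.  diag(A) = 1,  A PSD       (L = E - W)

with the package's ADMM solver (which also produces a certified dual
upper bound on the optimum), factor `A = V V'` by clamped LDL, and
round with random hyperplanes until the cut reaches 0.878 x bound.
The side with the smaller mean speckle distance becomes compartment A.
Per-cell binary profiles aggregate into the ensemble vector `c_ens`,
compartment frequency `f = c_ens - [c_ens < 0.5]`, normalized
frequency `f_norm = c_ens - 0.5` and variability
`delta_c = sqrt(c_ens (1 - c_ens))`.

Also included: contact- and distance-compartmentalization scores (CCS,
DCS), structural features (radial position, radius of gyration,
nuclear-body distances, interchromosomal contacts), baseline callers
(distance-matrix PCA, CG-content phasing, Hi-C PC1), a per-gene
transcription-ratio analysis, and a planted-truth synthetic generator.
See the vignette (`vignettes/single-cell-compartments.Rmd`) for the
full model description and design rationale.

## Worked example

```r
library(scMaxCut)

cfg <- syntheticConfig(nLoci = 40, nCells = 20, seed = 1)
sim <- simulatePopulation(cfg)                  # planted A/B blocks
res <- callCompartments(sim$population, rBead = 200, seed = 1)

mean(truthAccuracy(res$profiles, sim$truth))
#> [1] 0.9575

ens <- ensembleCompartments(res$profiles, tracePanel(sim$population))
ens
#> EnsembleCompartments over K = 20 cells, 40 bins; 17 majority-A, 23 majority-B
profileCorrelation(ens@fNorm, sim$truth)
#> [1] 0.9961876

scores <- scoreCompartments(sim$population, res$profiles, rBead = 200)
colMeans(scores[, c("ccs", "dcs")])
#>   ccs   dcs
#> 1.000 0.071
```

Reading: per-cell calls match the planted labels at 95.75% of bins,
the population normalized-frequency profile correlates with the
planted profile at r = 0.996, every spatial contact falls inside a
called compartment (CCS = 1), and intra-compartment pairs contribute
only 7% of total pairwise distance (DCS = 0.071; lower is better).

Real data enter through `readTraces()` (simple CSV or FOF-CT-like
chromatin-trace tables), and results leave through `writeCalls()` /
`writeEnsembleBedGraph()` (bedGraph + BED9). A thin command-line
wrapper with subcommands `simulate`, `call`, `ensemble`, `score`,
`baseline` and `compare` is installed at `inst/scripts/scmaxcut`.

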
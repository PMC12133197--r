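#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' ChromatinTrace: one chromosome copy in one cell
#'
#' Ordered loci of a single chromosome copy together with their 3D
#' coordinates and, optionally, distances to nuclear bodies. Coordinates
#' and distances are in nanometres. Loci are genomic bins (0-based,
#' half-open) carried as a \link[GenomicRanges]{GRanges} panel whose
#' \code{binIndex} metadata column is the 0-based position of each locus
#' along the panel; genomic separation in the graph weights is measured
#' in units of \code{binIndex}.
#'
#' @slot cellId character(1), cell identifier.
#' @slot homolog character(1), homolog identifier ("1" when unknown).
#' @slot panel \code{GRanges} of loci, sorted by start, with an integer
#'   \code{binIndex} metadata column.
#' @slot coords numeric matrix, one row per locus, columns x/y/z (nm);
#'   \code{NA} marks an unobserved locus before interpolation.
#' @slot speckleDist numeric, distance to the nearest nuclear speckle per
#'   locus (nm), or \code{numeric(0)} when absent.
#' @slot speckleIntensity numeric, imaged speckle-marker intensity per
#'   locus (arbitrary units), or \code{numeric(0)}.
#' @slot laminaDist numeric, distance to the nuclear lamina per locus
#'   (nm), or \code{numeric(0)}.
#'
#' @seealso [readTraces()], [interpolateMissing()], [buildGraph()]
#' @export
setClass("ChromatinTrace",
    representation(
        cellId = "character",
        homolog = "character",
        panel = "GRanges",
        coords = "matrix",
        speckleDist = "numeric",
        speckleIntensity = "numeric",
        laminaDist = "numeric"
    )
)

setValidity("ChromatinTrace", function(object) {
    n <- length(object@panel)
    msg <- character(0)
    if (length(object@cellId) != 1L)
        msg <- c(msg, "cellId must be a single string")
    if (nrow(object@coords) != n || ncol(object@coords) != 3L)
        msg <- c(msg, "coords must be an n x 3 matrix matching the panel")
    bi <- object@panel$binIndex
    if (is.null(bi) || any(diff(bi) <= 0))
        msg <- c(msg, "panel$binIndex must be present and strictly increasing")
    if (any(GenomicRanges::width(object@panel) < 1L))
        msg <- c(msg, "all bins must satisfy bin_end > bin_start")
    if (is.unsorted(GenomicRanges::start(object@panel)))
        msg <- c(msg, "loci must be sorted by bin_start")
    for (s in c("speckleDist", "speckleIntensity", "laminaDist")) {
        v <- slot(object, s)
        if (length(v) != 0L && length(v) != n)
            msg <- c(msg, sprintf("%s must have length 0 or n", s))
    }
    if (length(msg)) msg else TRUE
})

#' TracePopulation: single-cell traces sharing one locus panel
#'
#' A collection of \linkS4class{ChromatinTrace} objects (one chromosome
#' copy per trace) indexed on a common genomic bin panel.
#'
#' @slot panel shared \code{GRanges} locus panel.
#' @slot traces list of \code{ChromatinTrace}.
#' @slot resolution bin size in base pairs.
#'
#' @export
setClass("TracePopulation",
    representation(
        panel = "GRanges",
        traces = "list",
        resolution = "numeric"
    )
)

setValidity("TracePopulation", function(object) {
    msg <- character(0)
    if (length(object@traces) < 1L)
        msg <- c(msg, "population must contain at least one trace")
    ok <- vapply(object@traces, is, logical(1), "ChromatinTrace")
    if (!all(ok))
        msg <- c(msg, "all elements of traces must be ChromatinTrace")
    n <- length(object@panel)
    same <- vapply(object@traces, function(tr) length(tr@panel) == n &&
        all(GenomicRanges::start(tr@panel) == GenomicRanges::start(object@panel)),
        logical(1))
    if (!all(same))
        msg <- c(msg, "all traces must share the population panel")
    if (length(msg)) msg else TRUE
})

#' StructureGraph: weighted graph of one chromosome structure
#'
#' Symmetric edge-weight matrix in [0, 1] built from a single-cell
#' structure, with its degree vector and Laplacian \eqn{L = E - W}.
#'
#' @slot n node count.
#' @slot W symmetric adjacency matrix, zero diagonal, entries in [0, 1].
#' @slot degree row sums of \code{W}.
#' @slot laplacian Laplacian matrix \eqn{L = E - W}.
#' @slot keptEdges number of unordered node pairs surviving distance
#'   pruning.
#' @slot speckleZ per-node z-scored speckle distance.
#' @slot params list of graph-building parameters used.
#'
#' @export
setClass("StructureGraph",
    representation(
        n = "integer",
        W = "matrix",
        degree = "numeric",
        laplacian = "matrix",
        keptEdges = "integer",
        speckleZ = "numeric",
        params = "list"
    )
)

setValidity("StructureGraph", function(object) {
    msg <- character(0)
    W <- object@W
    if (nrow(W) != object@n || ncol(W) != object@n)
        msg <- c(msg, "W must be n x n")
    if (max(abs(W - t(W))) > 1e-12)
        msg <- c(msg, "W must be symmetric")
    if (any(diag(W) != 0))
        msg <- c(msg, "W must have a zero diagonal")
    if (min(W) < 0 || max(W) > 1 + 1e-12)
        msg <- c(msg, "weights must lie in [0, 1]")
    if (max(abs(rowSums(object@laplacian))) > 1e-9)
        msg <- c(msg, "Laplacian rows must sum to 0")
    if (length(msg)) msg else TRUE
})

#' SdpSolution: solved max-cut semidefinite relaxation
#'
#' @slot A symmetric matrix with unit diagonal, positive semidefinite to
#'   solver tolerance; the relaxed Gram matrix of node vectors.
#' @slot sdpObjective value of \eqn{(1/4)\,tr(L^T A)} at \code{A}.
#' @slot sdpBound certified upper bound on the relaxation optimum,
#'   obtained from a feasible dual point; satisfies
#'   \code{sdpObjective <= sdpBound}.
#' @slot converged logical, solver convergence flag.
#' @slot tolerance convergence tolerance used.
#' @slot iterations iterations performed.
#'
#' @export
setClass("SdpSolution",
    representation(
        A = "matrix",
        sdpObjective = "numeric",
        sdpBound = "numeric",
        converged = "logical",
        tolerance = "numeric",
        iterations = "integer"
    )
)

#' CutSolution: rounded graph bipartition
#'
#' @slot s label vector with entries +1/-1.
#' @slot objective achieved cut value \eqn{(1/4) s^T L s}.
#' @slot sdpBound upper bound carried from the SDP solution.
#' @slot nRounds hyperplane draws performed.
#' @slot thresholdRatio early-stop ratio relative to \code{sdpBound}.
#' @slot seed integer seed used for the draws (NA when the ambient RNG
#'   stream was used).
#'
#' @export
setClass("CutSolution",
    representation(
        s = "numeric",
        objective = "numeric",
        sdpBound = "numeric",
        nRounds = "integer",
        thresholdRatio = "numeric",
        seed = "integer"
    )
)

setValidity("CutSolution", function(object) {
    msg <- character(0)
    if (!all(object@s %in% c(-1, 1)))
        msg <- c(msg, "s entries must be +1 or -1")
    if (object@objective > object@sdpBound + 1e-6)
        msg <- c(msg, "cut value exceeds the SDP bound")
    if (length(msg)) msg else TRUE
})

#' CompartmentProfile: per-cell binary A/B calls
#'
#' @slot cellId cell identifier.
#' @slot homolog homolog identifier.
#' @slot calls integer vector, 1 = compartment A, 0 = compartment B.
#'
#' @export
setClass("CompartmentProfile",
    representation(
        cellId = "character",
        homolog = "character",
        calls = "integer"
    )
)

setValidity("CompartmentProfile", function(object) {
    if (!all(object@calls %in% c(0L, 1L)))
        "calls must be 0 (B) or 1 (A)" else TRUE
})

#' EnsembleCompartments: population-level compartment statistics
#'
#' Aggregates per-cell A/B calls over K structures into the ensemble
#' compartment vector (per-bin A fraction), the signed compartment
#' frequency, the normalized frequency, and the compartment variability.
#'
#' @slot panel shared locus panel.
#' @slot cEns per-bin fraction of cells calling A, in [0, 1].
#' @slot f compartment frequency: \code{cEns} where \code{cEns >= 0.5},
#'   \code{cEns - 1} elsewhere.
#' @slot fNorm normalized frequency \code{cEns - 0.5}.
#' @slot deltaC per-bin population standard deviation of the binary
#'   calls.
#' @slot K number of cells aggregated.
#'
#' @export
setClass("EnsembleCompartments",
    representation(
        panel = "GRanges",
        cEns = "numeric",
        f = "numeric",
        fNorm = "numeric",
        deltaC = "numeric",
        K = "integer"
    )
)

setValidity("EnsembleCompartments", function(object) {
    msg <- character(0)
    if (any(object@cEns < 0 | object@cEns > 1))
        msg <- c(msg, "cEns must lie in [0, 1]")
    if (any(abs(object@f) < 0.5 - 1e-12))
        msg <- c(msg, "|f| must be >= 0.5")
    if (any(object@deltaC < 0 | object@deltaC > 0.5 + 1e-12))
        msg <- c(msg, "deltaC must lie in [0, 0.5]")
    if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the planted-compartment generator
#'
#' Phenomenological two-attractor model of a chromosome in a spherical
#' nucleus: a Markov chain along the bins plants A/B blocks, each cell is
#' a sequential Gaussian random walk pulled toward its compartment's
#' attractor, and nuclear speckles sit at the A attractor, so A beads are
#' speckle-proximal by construction. See the package vignette for the
#' rationale behind each default.
#'
#' @slot nLoci number of genomic bins.
#' @slot nCells number of cells K.
#' @slot nHomologs chromosome copies per cell (2 enables the
#'   transcription-ratio analysis).
#' @slot resolution bin size, bp.
#' @slot switchProb probability the planted label flips between
#'   consecutive bins (expected block length 1/switchProb bins).
#' @slot separation distance between the A and B attractors, nm.
#' @slot stepSd random-walk step standard deviation per axis, nm.
#' @slot pull per-step attraction toward the bead's attractor, in [0, 1].
#' @slot nucleusRadius nm.
#' @slot nSpeckles speckles placed near the A attractor.
#' @slot speckleJitterSd speckle placement jitter, nm.
#' @slot speckleNoiseSd measurement noise added to speckle distances, nm.
#' @slot labelNoise probability a bead's geometry follows the wrong
#'   attractor (cell-to-cell variability).
#' @slot nGenes genes with simulated nascent transcript counts.
#' @slot rateA,rateB Poisson mean transcript counts for genes whose bin
#'   is A (resp. B) on both homologs.
#' @slot seed integer master seed; all randomness derives from it.
#'
#' @export
setClass("SyntheticConfig",
    representation(
        nLoci = "integer",
        nCells = "integer",
        nHomologs = "integer",
        resolution = "numeric",
        switchProb = "numeric",
        separation = "numeric",
        stepSd = "numeric",
        pull = "numeric",
        nucleusRadius = "numeric",
        nSpeckles = "integer",
        speckleJitterSd = "numeric",
        speckleNoiseSd = "numeric",
        labelNoise = "numeric",
        nGenes = "integer",
        rateA = "numeric",
        rateB = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character(0)
    for (s in c("switchProb", "pull", "labelNoise")) {
        v <- slot(object, s)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
    }
    if (object@separation <= 0 || object@stepSd <= 0 ||
        object@nucleusRadius <= 0)
        msg <- c(msg, "separation, stepSd and nucleusRadius must be > 0")
    if (object@separation > 2 * object@nucleusRadius)
        msg <- c(msg, "infeasible geometry: separation exceeds the nuclear diameter")
    if (object@rateB > object@rateA || object@rateB < 0)
        msg <- c(msg, "rates must satisfy rateA >= rateB >= 0")
    if (object@nLoci < 3L) msg <- c(msg, "nLoci must be >= 3")
    if (length(msg)) msg else TRUE
})
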
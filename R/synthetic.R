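#' Construct a synthetic-population configuration
#'
#' Builds a validated \linkS4class{SyntheticConfig}. Defaults describe a
#' 60-bin chromosome at 200 kb resolution in a 5 um-radius nucleus with
#' two compartment attractors 2 um apart, a strong pull (0.8) of each
#' bead toward its attractor, 5\% per-bead label noise and speckles at
#' the A attractor — the statistical structure the max-cut caller
#' exploits (intra-compartment proximity, A-speckle proximity) and
#' nothing else.
#'
#' @param nLoci,nCells,nHomologs,resolution,switchProb,separation
#'   see \linkS4class{SyntheticConfig}.
#' @param stepSd,pull,nucleusRadius,nSpeckles,speckleJitterSd see
#'   \linkS4class{SyntheticConfig}.
#' @param speckleNoiseSd,labelNoise,nGenes,rateA,rateB,seed see
#'   \linkS4class{SyntheticConfig}.
#' @return A \linkS4class{SyntheticConfig}.
#' @examples
#' syntheticConfig(nCells = 10)
#' @export
syntheticConfig <- function(nLoci = 60, nCells = 100, nHomologs = 1,
                            resolution = 2e5, switchProb = 0.1,
                            separation = 2000, stepSd = 150, pull = 0.8,
                            nucleusRadius = 5000, nSpeckles = 3,
                            speckleJitterSd = 200, speckleNoiseSd = 100,
                            labelNoise = 0.05, nGenes = 20, rateA = 10,
                            rateB = 2, seed = 1) {
    new("SyntheticConfig", nLoci = as.integer(nLoci),
        nCells = as.integer(nCells), nHomologs = as.integer(nHomologs),
        resolution = resolution, switchProb = switchProb,
        separation = separation, stepSd = stepSd, pull = pull,
        nucleusRadius = nucleusRadius, nSpeckles = as.integer(nSpeckles),
        speckleJitterSd = speckleJitterSd, speckleNoiseSd = speckleNoiseSd,
        labelNoise = labelNoise, nGenes = as.integer(nGenes),
        rateA = rateA, rateB = rateB, seed = as.integer(seed))
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Plant ground-truth compartment labels
#'
#' A two-state Markov chain along the bins with per-step flip
#' probability \code{switchProb}, giving geometrically distributed
#' block lengths with mean \code{1/switchProb} bins. Resamples until
#' both states are present (except at switchProb 0, where a single
#' block is the defined outcome).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return integer vector of 0/1 planted labels (1 = A).
#' @export
plantLabels <- function(config) {
    .withSeed(config@seed, {
        n <- config@nLoci
        p <- config@switchProb
        for (attempt in 1:100) {
            lab <- integer(n)
            lab[1] <- stats::rbinom(1, 1, 0.5)
            if (n > 1) {
                flips <- stats::runif(n - 1) < p
                lab[-1] <- (lab[1] + cumsum(flips)) %% 2L
            }
            if (p == 0 || length(unique(lab)) == 2L) break
        }
        if (length(unique(lab)) < 2L && p > 0)
            lab[seq_len(max(1L, n %/% 2L))] <- 1L - lab[1]
        as.integer(lab)
    })
}

.simulateTrace <- function(config, labels, cellSeed) {
    .withSeed(cellSeed, {
        n <- config@nLoci
        eff <- labels
        flip <- stats::runif(n) < config@labelNoise
        eff[flip] <- 1L - eff[flip]
        centerA <- c(-config@separation / 2, 0, 0)
        centerB <- c(config@separation / 2, 0, 0)
        ctr <- function(l) if (l == 1L) centerA else centerB
        X <- matrix(0, n, 3)
        X[1, ] <- ctr(eff[1]) + stats::rnorm(3, 0, config@stepSd)
        for (i in seq_len(n)[-1]) {
            prop <- X[i - 1, ] + stats::rnorm(3, 0, config@stepSd)
            X[i, ] <- prop + config@pull * (ctr(eff[i]) - prop)
        }
        nr <- sqrt(rowSums(X^2))
        over <- nr > config@nucleusRadius
        X[over, ] <- X[over, ] * (config@nucleusRadius / nr[over])
        spk <- matrix(rep(centerA, config@nSpeckles), ncol = 3,
            byrow = TRUE) +
            matrix(stats::rnorm(3 * config@nSpeckles, 0,
                config@speckleJitterSd), ncol = 3)
        cross <- outer(rowSums(X^2), rowSums(spk^2), "+") - 2 * X %*% t(spk)
        cross[cross < 0] <- 0
        spd <- apply(sqrt(cross), 1, min) +
            stats::rnorm(n, 0, config@speckleNoiseSd)
        list(X = X, spd = spd, eff = eff)
    })
}

#' Simulate a trace population with planted compartments
#'
#' Generates \code{nCells} cells (each with \code{nHomologs} chromosome
#' copies) under the two-attractor model of [syntheticConfig()]:
#' per-bead effective labels flip with probability \code{labelNoise}, a
#' sequential Gaussian random walk is pulled toward the bead's
#' attractor at each step, coordinates are clipped to the nuclear
#' sphere, speckle distances are measured to jittered speckles at the A
#' attractor with Gaussian measurement noise, and per-gene nascent
#' transcript counts are Poisson with mean \code{rateA} when the gene's
#' bin is effectively A on all homologs, \code{rateB} when B on all,
#' and the midpoint rate otherwise. All randomness derives
#' deterministically from \code{seed} via per-cell substreams, so the
#' first k cells of a K-cell run equal a k-cell run.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{population}
#'   (\linkS4class{TracePopulation}), \code{truth} (planted 0/1 labels),
#'   \code{counts} (long data.frame \code{cell_id}, \code{gene},
#'   \code{count}), \code{geneMap} (\code{gene}, \code{bin}) and
#'   \code{cg} (synthetic per-bin CG fractions, higher in A blocks).
#' @export
simulatePopulation <- function(config) {
    labels <- plantLabels(config)
    n <- config@nLoci
    panel <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = (seq_len(n) - 1L) * config@resolution + 1L,
            width = config@resolution))
    panel$binIndex <- seq_len(n) - 1L
    cg <- .withSeed(config@seed + 1L, {
        pmin(pmax(ifelse(labels == 1L, 0.55, 0.40) +
            stats::rnorm(n, 0, 0.02), 0), 1)
    })
    geneMap <- data.frame(
        gene = sprintf("gene%02d", seq_len(config@nGenes)),
        bin = as.integer(floor((seq_len(config@nGenes) - 0.5) * n /
            config@nGenes)))
    traceList <- list()
    effByCell <- vector("list", config@nCells)
    for (k in seq_len(config@nCells)) {
        effs <- matrix(0L, config@nHomologs, n)
        for (h in seq_len(config@nHomologs)) {
            sim <- .simulateTrace(config, labels,
                config@seed + 1000003L * k + h)
            tr <- new("ChromatinTrace",
                cellId = sprintf("cell%04d", k),
                homolog = as.character(h),
                panel = panel,
                coords = sim$X,
                speckleDist = sim$spd,
                speckleIntensity = numeric(0),
                laminaDist = numeric(0))
            traceList[[length(traceList) + 1L]] <- tr
            effs[h, ] <- sim$eff
        }
        effByCell[[k]] <- effs
    }
    counts <- .withSeed(config@seed + 2L, {
        rows <- lapply(seq_len(config@nCells), function(k) {
            effs <- effByCell[[k]][, geneMap$bin + 1L, drop = FALSE]
            allA <- colSums(effs == 1L) == nrow(effs)
            allB <- colSums(effs == 0L) == nrow(effs)
            rate <- ifelse(allA, config@rateA,
                ifelse(allB, config@rateB,
                    (config@rateA + config@rateB) / 2))
            data.frame(cell_id = sprintf("cell%04d", k),
                gene = geneMap$gene,
                count = stats::rpois(nrow(geneMap), rate))
        })
        do.call(rbind, rows)
    })
    list(
        population = new("TracePopulation", panel = panel,
            traces = traceList, resolution = config@resolution),
        truth = labels, counts = counts, geneMap = geneMap, cg = cg)
}

#' Accuracy of calls against planted labels
#'
#' Per-profile fraction of bins whose A/B call matches the planted
#' label. No label flipping is applied: both the caller and the
#' generator identify A through speckle proximity, so orientation is
#' already shared.
#'
#' @param profiles list of \linkS4class{CompartmentProfile}.
#' @param truth planted 0/1 labels.
#' @return numeric vector of per-profile accuracies in [0, 1].
#' @export
truthAccuracy <- function(profiles, truth) {
    vapply(profiles, function(p) {
        stopifnot(length(p@calls) == length(truth))
        mean(p@calls == truth)
    }, numeric(1))
}
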
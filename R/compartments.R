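#' Assign A/B identities to the two sides of a cut
#'
#' The cut bipartition is anonymous; biology fixes the orientation:
#' compartment A is transcriptionally active and speckle-proximal, so
#' the side with the smaller mean speckle distance becomes A. On an
#' exact tie the side containing the first node becomes A (logged).
#'
#' @param cut a \linkS4class{CutSolution}.
#' @param speckleDist per-node speckle distance (nm), aligned with the
#'   cut labels.
#' @param cellId,homolog identifiers stored in the profile.
#' @return A \linkS4class{CompartmentProfile} (1 = A, 0 = B).
#' @export
assignAB <- function(cut, speckleDist, cellId = "cell", homolog = "1") {
    s <- cut@s
    stopifnot(length(s) == length(speckleDist))
    plus <- s > 0
    if (all(plus) || all(!plus))
        stop("degenerate cut: one side of the partition is empty")
    mPlus <- mean(speckleDist[plus])
    mMinus <- mean(speckleDist[!plus])
    if (mPlus == mMinus) {
        message("speckle-distance tie; side containing the first node is A")
        aSide <- plus[1L]
    } else {
        aSide <- mPlus < mMinus
    }
    new("CompartmentProfile", cellId = cellId, homolog = homolog,
        calls = as.integer(plus == aSide))
}

.profileMatrix <- function(profiles) {
    stopifnot(length(profiles) >= 1L)
    n <- length(profiles[[1]]@calls)
    ok <- vapply(profiles, function(p) length(p@calls) == n, logical(1))
    if (!all(ok)) stop("profiles have mismatched panels")
    do.call(rbind, lapply(profiles, calls))
}

#' Ensemble compartment vector
#'
#' Per-bin fraction of structures calling the bin A:
#' \eqn{c^{ens} = (1/K)\sum_k c_k}.
#'
#' @param profiles list of \linkS4class{CompartmentProfile} on one
#'   panel.
#' @return numeric vector in [0, 1].
#' @export
ensembleVector <- function(profiles) {
    colMeans(.profileMatrix(profiles))
}

#' Compartment frequency
#'
#' Signed majority-compartment frequency
#' \eqn{f_i = c^{ens}_i - [c^{ens}_i < 0.5]}: positive values give the
#' A fraction of majority-A bins, negative values minus the B fraction
#' of majority-B bins, so \eqn{|f_i| \ge 0.5} always. Directly
#' comparable to a Hi-C PC1 profile.
#'
#' @param cEns ensemble compartment vector (entries in [0, 1]).
#' @return numeric vector in \eqn{[-1, -0.5) \cup [0.5, 1]}.
#' @export
compartmentFrequency <- function(cEns) {
    stopifnot(all(cEns >= 0 & cEns <= 1))
    cEns - as.numeric(cEns < 0.5)
}

#' Normalized compartment frequency
#'
#' \eqn{f^{norm}_i = c^{ens}_i - 0.5}; the centred A fraction used for
#' correlation with external PC1 profiles.
#'
#' @param cEns ensemble compartment vector.
#' @return numeric vector in [-0.5, 0.5].
#' @export
normalizedFrequency <- function(cEns) {
    stopifnot(all(cEns >= 0 & cEns <= 1))
    cEns - 0.5
}

#' Compartment variability
#'
#' Per-bin population (divide-by-K) standard deviation of the binary
#' calls: \eqn{\delta c_i = \sqrt{(1/K)\sum_k (c_{ki} - \bar c_i)^2}}.
#' For binary data this equals
#' \eqn{\sqrt{c^{ens}_i(1 - c^{ens}_i)}}.
#'
#' @param profiles list of \linkS4class{CompartmentProfile}.
#' @return numeric vector in [0, 0.5].
#' @export
compartmentVariability <- function(profiles) {
    C <- .profileMatrix(profiles)
    m <- colMeans(C)
    sqrt(colMeans((C - rep(m, each = nrow(C)))^2))
}

#' Aggregate per-cell calls into ensemble statistics
#'
#' @param profiles list of \linkS4class{CompartmentProfile}.
#' @param panel the shared locus panel.
#' @return An \linkS4class{EnsembleCompartments}.
#' @examples
#' sim <- simulatePopulation(syntheticConfig(nLoci = 12, nCells = 4))
#' res <- callCompartments(sim$population, rBead = 200, seed = 1)
#' ensembleCompartments(res$profiles, tracePanel(sim$population))
#' @export
ensembleCompartments <- function(profiles, panel) {
    cEns <- ensembleVector(profiles)
    stopifnot(length(cEns) == length(panel))
    new("EnsembleCompartments", panel = panel, cEns = cEns,
        f = compartmentFrequency(cEns),
        fNorm = normalizedFrequency(cEns),
        deltaC = compartmentVariability(profiles),
        K = length(profiles))
}

#' Per-gene transcription ratio between A and B cells
#'
#' For each gene (mapped to its nearest-promoter bin), cells are grouped
#' by the compartment call of that bin on both homologs: A cells carry
#' the bin in compartment A on both copies, B cells on neither. Before
#' grouping, the bottom 5\% of cells by that gene's transcript count are
#' removed to avoid zero-inflation. The ratio is
#' \eqn{trans = \log_2(t_A / t_B)} with \eqn{t_A, t_B} the mean counts
#' of each group; genes with an empty group (or \eqn{t_B = 0}) are
#' reported as \code{NA}, never imputed.
#'
#' @param profiles list of \linkS4class{CompartmentProfile} with
#'   \code{cellId} and \code{homolog} set; cells lacking both homologs
#'   are excluded.
#' @param counts data.frame with columns \code{cell_id}, \code{gene},
#'   \code{count}.
#' @param geneMap data.frame with columns \code{gene}, \code{bin}
#'   (0-based panel bin index of the gene's promoter). Genes mapping
#'   outside the panel are skipped with a warning.
#' @param bottomFrac fraction of lowest-count cells dropped per gene
#'   (default 0.05).
#' @return data.frame with one row per gene: \code{gene}, \code{n_A},
#'   \code{n_B}, \code{t_A}, \code{t_B}, \code{trans}.
#' @export
transcriptionRatio <- function(profiles, counts, geneMap,
                               bottomFrac = 0.05) {
    nBins <- length(profiles[[1]]@calls)
    cellsOf <- split(profiles, vapply(profiles, cellId, character(1)))
    paired <- Filter(function(ps) {
        length(unique(vapply(ps, homolog, character(1)))) >= 2L
    }, cellsOf)
    if (!length(paired))
        stop("no cell carries two homolog traces; cannot group cells")
    res <- lapply(unique(geneMap$gene), function(g) {
        bin <- geneMap$bin[match(g, geneMap$gene)]
        if (is.na(bin) || bin < 0L || bin >= nBins) {
            warning("gene ", g, " does not map to the locus panel; skipped")
            return(NULL)
        }
        cts <- counts[counts$gene == g, ]
        cts <- cts[cts$cell_id %in% names(paired), ]
        if (!nrow(cts)) return(NULL)
        nDrop <- floor(bottomFrac * nrow(cts))
        keep <- order(cts$count)[seq_len(nrow(cts))] # stable order
        if (nDrop > 0) keep <- keep[-seq_len(nDrop)]
        cts <- cts[keep, ]
        bothCall <- vapply(cts$cell_id, function(cid) {
            cc <- vapply(paired[[cid]], function(p) p@calls[bin + 1L],
                integer(1))
            if (all(cc == 1L)) 1L else if (all(cc == 0L)) 0L else NA_integer_
        }, integer(1))
        tA <- mean(cts$count[!is.na(bothCall) & bothCall == 1L])
        tB <- mean(cts$count[!is.na(bothCall) & bothCall == 0L])
        nA <- sum(!is.na(bothCall) & bothCall == 1L)
        nB <- sum(!is.na(bothCall) & bothCall == 0L)
        trans <- if (nA == 0L || nB == 0L || is.na(tB) || tB == 0) {
            NA_real_
        } else {
            log2(tA / tB)
        }
        data.frame(gene = g, n_A = nA, n_B = nB,
            t_A = if (nA) tA else NA_real_,
            t_B = if (nB) tB else NA_real_, trans = trans)
    })
    do.call(rbind, res[!vapply(res, is.null, logical(1))])
}
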
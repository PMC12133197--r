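#' Z-score speckle distances within a trace
#'
#' Standardizes the per-locus distance to the nearest nuclear speckle
#' within one chromosome copy: \eqn{z_i = (SpD_i - mean(SpD)) / sd(SpD)}
#' with the population (divide-by-n) standard deviation. When only
#' speckle-marker intensities are available they are first converted to
#' pseudo-distances with [intensityToPseudoDist()]; the z-scores are
#' scale-invariant, so the unknown proportionality constant of that
#' conversion drops out. A zero-variance input yields an all-zero
#' z vector.
#'
#' @param trace a \linkS4class{ChromatinTrace} carrying
#'   \code{speckleDist} or \code{speckleIntensity}.
#' @return numeric z-score vector, one entry per locus.
#' @export
speckleZScores <- function(trace) {
    spd <- trace@speckleDist
    if (!length(spd)) {
        if (length(trace@speckleIntensity)) {
            spd <- intensityToPseudoDist(trace@speckleIntensity)
        } else {
            stop("trace ", trace@cellId, " carries no speckle information; ",
                "supply speckle distances or marker intensities")
        }
    }
    .zscore(spd)
}

.zscore <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Convert speckle-marker intensity to a pseudo-distance
#'
#' Assumes the imaged speckle intensity decays quadratically with
#' distance, so \eqn{1/\sqrt{s_i}} is proportional to the distance to
#' the nearest speckle. Nonpositive intensities are floored to the
#' smallest positive observed value with a warning.
#'
#' @param intensity numeric vector of marker intensities (a.u.).
#' @return numeric pseudo-distance vector, monotone decreasing in the
#'   intensity.
#' @examples
#' intensityToPseudoDist(c(1, 4)) # 1, 0.5
#' @export
intensityToPseudoDist <- function(intensity) {
    if (all(intensity <= 0, na.rm = TRUE))
        stop("all speckle intensities are nonpositive")
    if (any(intensity <= 0, na.rm = TRUE)) {
        floorv <- min(intensity[intensity > 0], na.rm = TRUE)
        warning(sum(intensity <= 0, na.rm = TRUE),
            " nonpositive intensities floored to ", signif(floorv, 4))
        intensity[intensity <= 0] <- floorv
    }
    1 / sqrt(intensity)
}

#' Expected spatial distance for a genomic separation
#'
#' At short range the mean 3D distance between two loci grows as the
#' square root of their genomic separation, so the observed distance is
#' normalized by \eqn{e_{ij} = |g_i - g_j|^{1/2}} when forming edge
#' weights.
#'
#' @param gap genomic separation in bins (>= 1).
#' @return unitless expected-distance scale.
#' @export
expectedDistance <- function(gap) {
    stopifnot(all(gap >= 1))
    sqrt(gap)
}

#' Build the weighted graph of a single-cell structure
#'
#' Embeds one preprocessed chromosome trace as the undirected weighted
#' graph whose maximum cut separates the two compartments. For each
#' locus pair \eqn{i < j} the raw weight is the product
#' \deqn{w_{ij} = |z_i - z_j| \cdot \|x_i - x_j\|_2 / \sqrt{|g_i - g_j|}}
#' of the speckle-affinity dissimilarity, the observed 3D distance and
#' the inverse expected distance. Edges whose spatial distance exceeds
#' \code{pruneFactor * rBead} are removed (compartments are driven by
#' local structure), and the kept weights are min-max normalized by
#' their maximum so all weights lie in [0, 1].
#'
#' @param trace a preprocessed \linkS4class{ChromatinTrace}.
#' @param rBead bead radius in nm; 100 nm is the imaging-data default,
#'   modeled/synthetic structures require an explicit value.
#' @param pruneFactor distance-pruning multiple of \code{rBead}
#'   (default 16).
#' @param gapMode genomic separation measure: panel bin index
#'   (\code{"index"}, default) or \code{bin_start/resolution}
#'   (\code{"bp"}) for panels with heterogeneous spacing.
#' @param resolution bin size in bp, required for
#'   \code{gapMode = "bp"}.
#' @param epsilonZ constant added to \eqn{|z_i - z_j|}; 0 keeps the
#'   weight formula verbatim, a small positive value rescues degenerate
#'   inputs with tied z-scores.
#' @return A \linkS4class{StructureGraph}.
#' @examples
#' tp <- simulatePopulation(syntheticConfig(nLoci = 20, nCells = 1))$population
#' g <- buildGraph(traces(tp)[[1]], rBead = 200)
#' range(adjacency(g))
#' @export
buildGraph <- function(trace, rBead = 100, pruneFactor = 16,
                       gapMode = c("index", "bp"), resolution = NULL,
                       epsilonZ = 0) {
    gapMode <- match.arg(gapMode)
    stopifnot(rBead > 0, pruneFactor > 0)
    if (anyNA(trace@coords))
        stop("trace has missing coordinates; run interpolateMissing() first")
    z <- speckleZScores(trace)
    n <- nrow(trace@coords)
    g <- if (gapMode == "index") {
        as.numeric(trace@panel$binIndex)
    } else {
        if (is.null(resolution))
            stop("gapMode = 'bp' requires a resolution")
        (GenomicRanges::start(trace@panel) - 1) / resolution
    }
    D <- unname(as.matrix(stats::dist(trace@coords)))
    gap <- abs(outer(g, g, "-"))
    e <- sqrt(gap)
    diag(e) <- 1 # diagonal never queried; avoids 0/0
    w <- (abs(outer(z, z, "-")) + epsilonZ) * D / e
    diag(w) <- 0
    pruned <- D > pruneFactor * rBead
    w[pruned] <- 0
    keptEdges <- as.integer((sum(!pruned) - n) / 2)
    wmax <- max(w)
    if (wmax == 0)
        stop("degenerate graph: all edge weights are zero (constant ",
            "speckle z-scores, or every pair pruned)")
    W <- w / wmax
    deg <- rowSums(W)
    L <- diag(deg) - W
    gr <- new("StructureGraph", n = as.integer(n), W = W, degree = deg,
        laplacian = L, keptEdges = keptEdges, speckleZ = z,
        params = list(rBead = rBead, pruneFactor = pruneFactor,
            gapMode = gapMode, epsilonZ = epsilonZ))
    if (!.isConnected(W))
        message("graph for trace ", trace@cellId, " is disconnected")
    gr
}

.isConnected <- function(W) {
    n <- nrow(W)
    seen <- logical(n)
    frontier <- 1L
    seen[1L] <- TRUE
    while (length(frontier)) {
        nxt <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0 & !seen)
        seen[nxt] <- TRUE
        frontier <- nxt
    }
    all(seen)
}
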
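#' Radial position of loci in a spherical nucleus
#'
#' \eqn{r_i = \|x_i - center\|_2 / R_{nuc}}: 0 at the nuclear centre,
#' 1 at the surface.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param center nucleus centre; the origin for modeled structures, the
#'   cell centroid is a sensible choice for imaging data.
#' @param rNuc nucleus radius in nm (default 5000 nm = 5 um).
#' @return numeric vector of radial positions.
#' @export
radialPosition <- function(coords, center = c(0, 0, 0), rNuc = 5000) {
    stopifnot(rNuc > 0)
    sqrt(rowSums(sweep(coords, 2, center)^2)) / rNuc
}

#' Radial position variability per bin
#'
#' \eqn{\Delta r_i = \log_2(\sigma_i / \bar\sigma)} with
#' \eqn{\sigma_i} the across-cell population standard deviation of the
#' radial position of bin i and \eqn{\bar\sigma} the mean of
#' \eqn{\sigma} over the chromosome's bins.
#'
#' @param radials K x N matrix of radial positions (cells x bins).
#' @return numeric vector of log2 variability per bin.
#' @export
radialVariability <- function(radials) {
    stopifnot(nrow(radials) >= 2L)
    sigma <- apply(radials, 2, .popSd)
    sbar <- mean(sigma)
    if (sbar == 0) stop("all bins have zero radial variance")
    log2(sigma / sbar)
}

.popSd <- function(v) sqrt(mean((v - mean(v))^2))

#' Sliding-window radius of gyration
#'
#' Local chromatin compaction at each locus: the radius of gyration of
#' the window of \code{windowBins} consecutive beads centred on the
#' locus, \eqn{g = \sqrt{(1/m)\sum_j d_j^2}} with \eqn{d_j} the
#' distance of bead j to the window's centre of mass. The default
#' 5-bin window spans 1 Mb at 200 kb resolution. Windows are shrunk at
#' the chromosome ends.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param windowBins odd window width in bins (default 5).
#' @return numeric vector, one radius of gyration (nm) per locus.
#' @export
radiusOfGyration <- function(coords, windowBins = 5L) {
    stopifnot(windowBins %% 2L == 1L)
    n <- nrow(coords)
    half <- (windowBins - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
        w <- max(1L, i - half):min(n, i + half)
        X <- coords[w, , drop = FALSE]
        com <- colMeans(X)
        sqrt(mean(rowSums(sweep(X, 2, com)^2)))
    }, numeric(1))
}

#' Interchromosomal contact counts
#'
#' For each bin of each chromosome in one cell, the number of bins on
#' other chromosomes within \code{rSoft}.
#'
#' @param cellTraces list of \linkS4class{ChromatinTrace}, the
#'   chromosomes of one cell (>= 2, else an error).
#' @param rSoft contact range in nm (default 1000).
#' @return list of integer count vectors, one per input trace.
#' @export
interchromContacts <- function(cellTraces, rSoft = 1000) {
    if (length(cellTraces) < 2L)
        stop("interchromosomal contacts need at least two chromosomes")
    coords <- lapply(cellTraces, function(tr) tr@coords)
    lapply(seq_along(coords), function(i) {
        other <- do.call(rbind, coords[-i])
        X <- coords[[i]]
        cross <- outer(rowSums(X^2), rowSums(other^2), "+") -
            2 * X %*% t(other)
        cross[cross < 0] <- 0
        as.integer(rowSums(sqrt(cross) <= rSoft))
    })
}

#' Contact compartmentalization score (CCS)
#'
#' The fraction of spatial contacts falling within a compartment:
#' \eqn{s_c = n_{intra} / (n_{intra} + n_{inter})}, with a contact
#' defined as a pair at distance at most
#' \code{cutoffFactor * rBead} (3 bead radii for modeled and
#' seqFISH+-resolution structures, 4 for MERFISH resolution).
#' Sequence-adjacent pairs count as contacts by default. Higher is
#' better: a good partition keeps contacts inside compartments.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param calls per-locus 0/1 compartment labels.
#' @param rBead bead radius, nm.
#' @param cutoffFactor contact cutoff in bead radii (default 3).
#' @param includeAdjacent count sequence-adjacent pairs (default TRUE).
#' @return \eqn{s_c \in [0, 1]}, or \code{NA} when the structure has no
#'   contacts.
#' @export
contactScore <- function(coords, calls, rBead, cutoffFactor = 3,
                         includeAdjacent = TRUE) {
    stopifnot(nrow(coords) == length(calls), rBead > 0, cutoffFactor > 0)
    D <- as.matrix(stats::dist(coords))
    contact <- D <= cutoffFactor * rBead
    diag(contact) <- FALSE
    if (!includeAdjacent) {
        n <- nrow(D)
        adj <- abs(outer(seq_len(n), seq_len(n), "-")) == 1L
        contact[adj] <- FALSE
    }
    same <- outer(calls, calls, "==")
    nIntra <- sum(contact & same) / 2
    nInter <- sum(contact & !same) / 2
    if (nIntra + nInter == 0) return(NA_real_)
    nIntra / (nIntra + nInter)
}

#' Distance compartmentalization score (DCS)
#'
#' \eqn{s_d = d_{intra} / (d_{intra} + d_{inter})} with
#' \eqn{d_{intra}, d_{inter}} the sums of pairwise distances within and
#' between compartments. Lower is better: compact compartments keep the
#' intra-compartment share of total distance small. A mean-based
#' variant (averaging instead of summing, which removes the dependence
#' on group sizes) is available via \code{useMean}.
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param calls per-locus 0/1 compartment labels; both compartments
#'   must be non-empty, else \code{NA}.
#' @param useMean use mean rather than summed distances.
#' @return \eqn{s_d \in [0, 1]}, or \code{NA} when undefined.
#' @export
distanceScore <- function(coords, calls, useMean = FALSE) {
    stopifnot(nrow(coords) == length(calls))
    if (length(unique(calls)) < 2L) return(NA_real_)
    D <- as.matrix(stats::dist(coords))
    same <- outer(calls, calls, "==")
    diag(same) <- NA
    agg <- if (useMean) {
        function(v) mean(v, na.rm = TRUE)
    } else {
        function(v) sum(v, na.rm = TRUE) / 2
    }
    dIntra <- agg(D[same %in% TRUE])
    dInter <- agg(D[same %in% FALSE])
    if (dIntra + dInter == 0) return(NA_real_) # all points coincident
    dIntra / (dIntra + dInter)
}

#' Speckle-distance variability per bin
#'
#' Across-cell population standard deviation of the speckle distance of
#' each bin.
#'
#' @param spd K x N matrix of speckle distances (cells x bins), nm.
#' @return numeric vector, nm.
#' @export
speckleVariability <- function(spd) {
    stopifnot(nrow(spd) >= 2L)
    apply(spd, 2, .popSd)
}

#' Compartmentalization scores for a called population
#'
#' Computes per-trace CCS and DCS for a set of compartment profiles.
#'
#' @param population a \linkS4class{TracePopulation}.
#' @param profiles matching list of \linkS4class{CompartmentProfile}.
#' @param rBead bead radius, nm.
#' @param cutoffFactor contact cutoff in bead radii (default 3).
#' @return data.frame with columns \code{cell_id}, \code{homolog},
#'   \code{ccs}, \code{dcs}.
#' @export
scoreCompartments <- function(population, profiles, rBead,
                              cutoffFactor = 3) {
    trs <- traces(population)
    stopifnot(length(trs) == length(profiles))
    rows <- Map(function(tr, p) {
        data.frame(cell_id = p@cellId, homolog = p@homolog,
            ccs = contactScore(tr@coords, p@calls, rBead = rBead,
                cutoffFactor = cutoffFactor),
            dcs = distanceScore(tr@coords, p@calls))
    }, trs, profiles)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
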
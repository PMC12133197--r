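#' Power-law fit of mean distance versus genomic separation
#'
#' Ordinary least squares in log-log space:
#' \eqn{\log d = \log a + b \log(gap)}, the scaling used to normalize
#' mean distance matrices before PCA.
#'
#' @param meanDist mean spatial distances (nm), positive.
#' @param gaps matching genomic separations in bins, positive.
#' @return named vector \code{c(a, b)}.
#' @examples
#' g <- 1:20
#' powerlawFit(2 * sqrt(g), g) # a = 2, b = 0.5
#' @export
powerlawFit <- function(meanDist, gaps) {
    stopifnot(length(meanDist) == length(gaps))
    if (any(meanDist <= 0)) stop("distances must be positive")
    if (length(unique(gaps)) < 3L) stop("need at least 3 distinct gaps")
    fit <- stats::lm.fit(cbind(1, log(gaps)), log(meanDist))
    c(a = exp(fit$coefficients[[1]]), b = fit$coefficients[[2]])
}

.meanDistanceMatrix <- function(population) {
    trs <- traces(population)
    n <- nLoci(population)
    acc <- matrix(0, n, n)
    for (tr in trs) acc <- acc + as.matrix(stats::dist(tr@coords))
    acc / length(trs)
}

.orientLabels <- function(memberPos, population = NULL, cg = NULL) {
    # returns TRUE when the positive-sign group should be A
    if (!is.null(population)) {
        spd <- vapply(traces(population), function(tr) {
            if (length(tr@speckleDist)) tr@speckleDist else
                rep(NA_real_, nLoci(population))
        }, numeric(nLoci(population)))
        mspd <- rowMeans(spd, na.rm = TRUE)
        if (!all(is.nan(mspd))) {
            return(mean(mspd[memberPos]) < mean(mspd[!memberPos]))
        }
    }
    if (!is.null(cg)) return(mean(cg[memberPos]) > mean(cg[!memberPos]))
    stop("cannot orient A/B: supply speckle distances or a CG track")
}

#' Ensemble compartment calling by distance-matrix PCA
#'
#' The population mean pairwise distance matrix is normalized by the
#' expected distance at each genomic separation (a fitted power law),
#' converted to a Pearson correlation matrix of its rows, and the sign
#' pattern of the leading eigenvector splits the bins into two groups.
#' The group with the smaller mean speckle distance (falling back to
#' higher CG content) is A. The single annotation applies to all cells
#' of the ensemble.
#'
#' @param population a \linkS4class{TracePopulation} with >= 2 traces.
#' @param cg optional per-bin CG fractions for orientation fallback.
#' @return list with \code{labels} (0/1 per bin), \code{pc1} (unit-norm
#'   leading eigenvector), \code{fit} (power-law \code{c(a, b)}),
#'   \code{meanDist} and \code{normalized} matrices.
#' @export
distancePca <- function(population, cg = NULL) {
    if (length(traces(population)) < 2L)
        stop("distance PCA needs at least 2 traces")
    M <- .meanDistanceMatrix(population)
    n <- nrow(M)
    gap <- abs(outer(seq_len(n), seq_len(n), "-"))
    ut <- upper.tri(M)
    fit <- powerlawFit(M[ut], gap[ut])
    Nrm <- M / (fit["a"] * gap^fit["b"])
    diag(Nrm) <- NA # 0/0 at zero separation; excluded pairwise
    C <- stats::cor(Nrm, use = "pairwise.complete.obs")
    if (anyNA(C)) stop("constant rows in the normalized distance matrix")
    pc1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    memberPos <- pc1 >= 0
    if (all(memberPos) || all(!memberPos))
        stop("leading eigenvector does not split the bins")
    posIsA <- .orientLabels(memberPos, population = population, cg = cg)
    labels <- as.integer(memberPos == posIsA)
    list(labels = labels, pc1 = pc1 / sqrt(sum(pc1^2)), fit = fit,
        meanDist = M, normalized = Nrm)
}

#' Per-cell compartment calling by CG-content phasing
#'
#' Labels each locus of one cell by the CG content of its spatial
#' neighborhood: the smoothed CG of a locus is the mean CG over all
#' loci (itself included) within \code{radius}, and the locus is called
#' A when the log2 fold change of its smoothed CG against the reference
#' mean is strictly positive. The reference mean is the same-cell
#' chromosome-wide mean of smoothed CG by default.
#'
#' @param trace a preprocessed \linkS4class{ChromatinTrace}.
#' @param cg per-bin CG fraction.
#' @param radius neighborhood radius in nm (default 250).
#' @param referenceMean either the string \code{"cell"} (default) or a
#'   number to use as the reference (e.g. a population-wide mean).
#' @return list with \code{labels} (0/1), \code{smoothed} CG and
#'   \code{lfc}.
#' @export
cgPhasing <- function(trace, cg, radius = 250, referenceMean = "cell") {
    n <- nrow(trace@coords)
    stopifnot(length(cg) == n)
    D <- as.matrix(stats::dist(trace@coords))
    smoothed <- vapply(seq_len(n), function(i) {
        mean(cg[D[i, ] <= radius]) # self included (D[i,i] = 0)
    }, numeric(1))
    ref <- if (identical(referenceMean, "cell")) {
        mean(smoothed)
    } else {
        as.numeric(referenceMean)
    }
    lfc <- log2(smoothed / ref)
    list(labels = as.integer(lfc > 0), smoothed = smoothed, lfc = lfc)
}

#' PC1 compartment profile of a dense Hi-C matrix
#'
#' Leading principal component of a dense ensemble contact matrix: the
#' matrix is optionally converted to its Pearson correlation matrix,
#' then the eigenvector of the largest eigenvalue of the covariance
#' matrix is extracted. Comparison utility for user-supplied matrices.
#'
#' @param M square symmetric nonnegative contact matrix.
#' @param useCorrelation correlation-transform first (default TRUE).
#' @param orientation optional per-bin vector whose high values mark A
#'   (e.g. CG content, or minus mean speckle distance); fixes the sign
#'   of the eigenvector so positive entries are A.
#' @return list with \code{pc1} (unit norm) and \code{labels} (0/1, or
#'   \code{NULL} when no orientation vector is given).
#' @export
hicPca <- function(M, useCorrelation = TRUE, orientation = NULL) {
    if (nrow(M) != ncol(M)) stop("matrix must be square")
    if (max(abs(M - t(M))) > 1e-8) stop("matrix must be symmetric")
    X <- if (useCorrelation) stats::cor(M) else M
    pc1 <- eigen(stats::cov(X), symmetric = TRUE)$vectors[, 1]
    pc1 <- pc1 / sqrt(sum(pc1^2))
    labels <- NULL
    if (!is.null(orientation)) {
        memberPos <- pc1 >= 0
        if (!all(memberPos) && any(memberPos)) {
            posIsA <- mean(orientation[memberPos]) >
                mean(orientation[!memberPos])
            if (!posIsA) pc1 <- -pc1
            labels <- as.integer(pc1 >= 0)
        }
    }
    list(pc1 = pc1, labels = labels)
}

#' Pearson correlation between compartment profiles
#'
#' Correlation restricted to bins where both profiles are defined and
#' the prediction is non-zero, the convention used when comparing a
#' normalized compartment frequency with an external PC1 profile.
#'
#' @param pred predicted profile (e.g. normalized compartment
#'   frequency).
#' @param ref reference profile (e.g. Hi-C PC1).
#' @return Pearson r.
#' @export
profileCorrelation <- function(pred, ref) {
    stopifnot(length(pred) == length(ref))
    use <- is.finite(pred) & is.finite(ref) & pred != 0
    if (sum(use) < 3L) stop("fewer than 3 usable bins")
    stats::cor(pred[use], ref[use])
}
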
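#' Solve the max-cut semidefinite relaxation
#'
#' Maximizes \eqn{(1/4)\,tr(L^T A)} over symmetric positive semidefinite
#' matrices with unit diagonal — the Goemans-Williamson relaxation of
#' the maximum cut of the graph with Laplacian \eqn{L}. The solver is an
#' ADMM operator-splitting scheme alternating a linear update under the
#' unit-diagonal constraint with a projection onto the positive
#' semidefinite cone, with residual balancing of the penalty parameter.
#'
#' The returned primal matrix is rescaled to an exact unit diagonal (a
#' congruence by \eqn{diag(A)^{-1/2}}), so it is always feasible and its
#' objective never exceeds the true relaxation optimum. In addition a
#' certified upper bound on the optimum is computed from the dual: with
#' \eqn{y_i = (LA)_{ii}/4}, shifting every \eqn{y_i} by the most
#' negative eigenvalue of \eqn{diag(y) - L/4} gives a feasible dual
#' point whose value \eqn{\sum_i y_i} bounds the relaxation (and hence
#' the true maximum cut) from above, independently of solver accuracy.
#'
#' @param L symmetric graph Laplacian (positive semidefinite, zero row
#'   sums).
#' @param tolerance convergence tolerance on the scaled primal and dual
#'   residuals (default 1e-6). On non-convergence the solve is retried
#'   once at 1e-4 before failing.
#' @param maxIter iteration cap per attempt.
#' @return An \linkS4class{SdpSolution}.
#' @examples
#' L <- matrix(c(1, -1, -1, 1), 2) # single unit edge
#' solveSdp(L)@sdpObjective # ~1
#' @export
solveSdp <- function(L, tolerance = 1e-6, maxIter = 5000L) {
    if (max(abs(L - t(L))) > 1e-8) stop("L must be symmetric")
    n <- nrow(L)
    for (tol in unique(c(tolerance, 1e-4))) {
        res <- .admmMaxcutSdp(L, tol, maxIter)
        if (res$converged) break
        if (tol == tolerance && tolerance < 1e-4)
            warning("SDP solver did not converge at tolerance ", tolerance,
                "; retrying at 1e-4")
    }
    if (!res$converged)
        stop("SDP solver failed to converge within ", maxIter,
            " iterations (final residuals ", signif(res$rp, 3), "/",
            signif(res$rd, 3), ")")
    A <- res$Z
    d <- diag(A)
    d[d < 1e-12] <- 1
    A <- A / sqrt(d %o% d) # exact unit diagonal, stays PSD
    diag(A) <- 1
    obj <- sum(L * A) / 4
    y <- rowSums(L * A) / 4 # diag(L %*% A) / 4
    lmin <- min(eigen(diag(y) - L / 4, symmetric = TRUE,
        only.values = TRUE)$values)
    bound <- sum(y) - n * min(lmin, 0)
    new("SdpSolution", A = A, sdpObjective = obj,
        sdpBound = max(bound, obj), converged = res$converged,
        tolerance = tol, iterations = res$iter)
}

.admmMaxcutSdp <- function(L, tol, maxIter) {
    n <- nrow(L)
    C <- L / 4
    rho <- max(1e-8, norm(C, "F") / n)
    Z <- diag(n)
    U <- matrix(0, n, n)
    rp <- rd <- Inf
    conv <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        X <- Z - U + C / rho
        diag(X) <- 1
        ee <- eigen(X + U, symmetric = TRUE)
        pos <- ee$values > 0
        Znew <- if (any(pos)) {
            V <- ee$vectors[, pos, drop = FALSE]
            V %*% (ee$values[pos] * t(V))
        } else {
            matrix(0, n, n)
        }
        rp <- norm(X - Znew, "F")
        rd <- rho * norm(Znew - Z, "F")
        Z <- Znew
        U <- U + X - Z
        if (rp < tol * n && rd < tol * n) {
            conv <- TRUE
            break
        }
        if (it %% 50L == 0L) { # residual balancing
            if (rp > 10 * rd) {
                rho <- rho * 2
                U <- U / 2
            } else if (rd > 10 * rp) {
                rho <- rho / 2
                U <- U * 2
            }
        }
    }
    list(Z = Z, converged = conv, iter = it, rp = rp, rd = rd)
}

#' Factor a near-PSD Gram matrix into node vectors
#'
#' Recovers node vectors \eqn{V'} with \eqn{A' = V'V'^T \approx A} from
#' the solved relaxation. A Cholesky factorization would require strict
#' positive semidefiniteness, which solver tolerance does not guarantee,
#' so a root-free LDL factorization \eqn{A = U D U^T} (unit
#' lower-triangular \eqn{U}) is used instead and negative entries of
#' \eqn{D} are clamped to zero: \eqn{V' = U\sqrt{D'}}. The
#' reconstruction error \eqn{\|V'V'^T - A\|} is controlled by the
#' clamped mass, so a nearly-PSD input gives nearly-exact vectors.
#'
#' @param A symmetric matrix, approximately positive semidefinite, unit
#'   diagonal not required.
#' @return list with \code{V} (the n x n factor), \code{d} (LDL
#'   diagonal before clamping) and \code{clamped} (total negative mass
#'   set to zero).
#' @examples
#' f <- approxFactorize(diag(3))
#' f$V # identity
#' @export
approxFactorize <- function(A) {
    if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
    n <- nrow(A)
    U <- diag(n)
    d <- numeric(n)
    M <- A
    # pivots below this magnitude are treated as zero: eliminating with a
    # tiny (possibly negative) pivot of a near-PSD matrix is the unstable
    # case the clamping exists for
    piv <- 1e-10 * max(1, max(abs(diag(A))))
    for (j in seq_len(n)) {
        d[j] <- M[j, j]
        if (j < n) {
            rest <- (j + 1L):n
            if (abs(d[j]) > piv) {
                l <- M[rest, j] / d[j]
                U[rest, j] <- l
                M[rest, rest] <- M[rest, rest] - outer(l, M[rest, j])
            }
        }
    }
    dp <- pmax(d, 0)
    list(V = U * rep(sqrt(dp), each = n), d = d, clamped = -sum(d[d < 0]))
}

#' Cut value of a +/-1 labeling
#'
#' \eqn{(1/4) s^T L s}: the total weight of edges crossing the
#' bipartition encoded by \code{s}.
#'
#' @param s vector with entries +1/-1.
#' @param L graph Laplacian.
#' @return the cut value.
#' @export
cutObjective <- function(s, L) {
    if (!all(s %in% c(-1, 1))) stop("s entries must be +1 or -1")
    sum(s * (L %*% s)) / 4
}

#' Randomized hyperplane rounding
#'
#' Draws standard-normal vectors \eqn{r} and labels node \eqn{i} by the
#' sign of \eqn{v'_i \cdot r} (ties broken to +1), keeping the best cut
#' over draws. Drawing stops once the cut reaches
#' \code{thresholdRatio * sdpBound} — the Goemans-Williamson 0.878
#' guarantee expressed against the relaxation bound, which upper-bounds
#' the unknown optimum — or after \code{maxRounds} draws, in which case
#' the best cut found is returned with a warning.
#'
#' @param V node-vector matrix (rows are node vectors), e.g. from
#'   [approxFactorize()].
#' @param L graph Laplacian.
#' @param sdpBound upper bound from [solveSdp()].
#' @param thresholdRatio early-stop ratio (default 0.878); 1 disables
#'   early stopping so all \code{maxRounds} draws are used.
#' @param maxRounds maximum hyperplane draws (default 1000).
#' @param seed integer seed for reproducible draws; \code{NULL} uses the
#'   ambient RNG stream.
#' @return A \linkS4class{CutSolution}.
#' @examples
#' L <- matrix(c(1, -1, -1, 1), 2)
#' V <- approxFactorize(solveSdp(L)@A)$V
#' roundHyperplane(V, L, sdpBound = 1, seed = 1)@objective # 1
#' @export
roundHyperplane <- function(V, L, sdpBound, thresholdRatio = 0.878,
                            maxRounds = 1000L, seed = NULL) {
    stopifnot(nrow(V) == nrow(L), thresholdRatio > 0, thresholdRatio <= 1)
    n <- nrow(V)
    p <- ncol(V)
    maxRounds <- as.integer(maxRounds)
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv()))
        set.seed(seed)
    }
    target <- thresholdRatio * sdpBound
    best <- -Inf
    bestS <- NULL
    nRounds <- 0L
    batch <- 64L
    hitTarget <- FALSE
    while (nRounds < maxRounds && !hitTarget) {
        m <- min(batch, maxRounds - nRounds)
        # column j is the j-th sequential N(0, I_p) draw
        R <- matrix(stats::rnorm(p * m), p, m)
        S <- sign(V %*% R)
        S[S == 0] <- 1
        objs <- colSums(S * (L %*% S)) / 4
        hit <- which(objs >= target - 1e-12)
        if (length(hit)) {
            k <- hit[1L]
            nRounds <- nRounds + k
            hitTarget <- TRUE
        } else {
            k <- which.max(objs)
            nRounds <- nRounds + m
        }
        if (objs[k] > best) {
            best <- objs[k]
            bestS <- S[, k]
        }
    }
    if (!hitTarget && thresholdRatio < 1)
        warning("rounding exhausted ", maxRounds, " draws below ",
            "threshold (best ratio ",
            signif(best / max(sdpBound, .Machine$double.eps), 4), ")")
    new("CutSolution", s = as.numeric(bestS), objective = best,
        sdpBound = sdpBound, nRounds = as.integer(nRounds),
        thresholdRatio = thresholdRatio,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Exact maximum cut by exhaustive enumeration
#'
#' Enumerates all \eqn{2^{n-1}} bipartitions; the test oracle for the
#' relaxation-plus-rounding pipeline. Refuses graphs with more than 22
#' nodes.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return list with \code{s} (an optimal +/-1 labeling, last node
#'   fixed to +1) and \code{opt} (the maximum cut value).
#' @examples
#' W <- matrix(1, 3, 3); diag(W) <- 0
#' bruteForceMaxCut(W)$opt # 2
#' @export
bruteForceMaxCut <- function(W) {
    n <- nrow(W)
    if (n > 22L) stop("brute force refused for n > 22")
    if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
    L <- diag(rowSums(W)) - W
    total <- 2^(n - 1)
    chunk <- 8192
    best <- -Inf
    bestS <- rep(1, n)
    m0 <- 0
    while (m0 < total) {
        ms <- m0:min(m0 + chunk - 1, total - 1)
        # bit b of m encodes the sign of node b+1; node n fixed at +1
        S <- matrix(1, n, length(ms))
        for (b in seq_len(n - 1L)) {
            S[b, ] <- 2 * ((ms %/% 2^(b - 1)) %% 2) - 1
        }
        objs <- colSums(S * (L %*% S)) / 4
        k <- which.max(objs)
        if (objs[k] > best) {
            best <- objs[k]
            bestS <- S[, k]
        }
        m0 <- m0 + chunk
    }
    list(s = bestS, opt = best)
}

#' Cut one structure graph end to end
#'
#' Convenience wrapper chaining [solveSdp()], [approxFactorize()] and
#' [roundHyperplane()] on a \linkS4class{StructureGraph}.
#'
#' @param graph a \linkS4class{StructureGraph}.
#' @param tolerance,thresholdRatio,maxRounds,seed passed through.
#' @return A \linkS4class{CutSolution}.
#' @export
maxCut <- function(graph, tolerance = 1e-6, thresholdRatio = 0.878,
                   maxRounds = 1000L, seed = NULL) {
    sdp <- solveSdp(laplacian(graph), tolerance = tolerance)
    V <- approxFactorize(sdp@A)$V
    roundHyperplane(V, laplacian(graph), sdpBound = sdp@sdpBound,
        thresholdRatio = thresholdRatio, maxRounds = maxRounds, seed = seed)
}
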
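test_that("SDP matches closed-form optima on tiny graphs", {
    # single unit edge: rank-1 optimum A = [[1,-1],[-1,1]], value 1
    L <- matrix(c(1, -1, -1, 1), 2)
    sol <- solveSdp(L)
    expect_true(sol@converged)
    expect_equal(sol@sdpObjective, 1, tolerance = 1e-4)
    expect_equal(sol@A[1, 2], -1, tolerance = 1e-3)
    # unit triangle: vectors at 120 degrees, off-diagonals -1/2, value 9/4
    W <- matrix(1, 3, 3)
    diag(W) <- 0
    sol3 <- solveSdp(graphLaplacian(W))
    expect_equal(sol3@sdpObjective, 2.25, tolerance = 1e-3)
    expect_equal(sol3@A[upper.tri(sol3@A)], rep(-0.5, 3), tolerance = 1e-2)
    # empty graph
    sol0 <- solveSdp(matrix(0, 3, 3))
    expect_equal(sol0@sdpObjective, 0)
})

test_that("SDP solution is feasible and bounded by its dual certificate", {
    set.seed(4)
    for (n in c(6, 11)) {
        L <- graphLaplacian(randomGraph(n))
        sol <- solveSdp(L)
        expect_lt(max(abs(diag(sol@A) - 1)), 1e-6)
        expect_equal(sol@A, t(sol@A))
        ev <- eigen(sol@A, symmetric = TRUE, only.values = TRUE)$values
        expect_gt(min(ev), -sol@tolerance * n)
        expect_lte(sol@sdpObjective, sol@sdpBound + 1e-9)
    }
})

test_that("LDL factorization reproduces PSD inputs and clamps tiny negatives", {
    expect_equal(approxFactorize(diag(3))$V, diag(3))
    A <- matrix(c(1, -1, -1, 1), 2)
    f <- approxFactorize(A)
    expect_lt(max(abs(f$V %*% t(f$V) - A)), 1e-9)
    # perturbed fixture: one eigenvalue pushed to -1e-9
    set.seed(5)
    Q <- qr.Q(qr(matrix(rnorm(16), 4)))
    Ap <- Q %*% diag(c(1.5, 1, 0.3, -1e-9)) %*% t(Q)
    Ap <- (Ap + t(Ap)) / 2
    fp <- approxFactorize(Ap)
    expect_gte(fp$clamped, 0)
    err <- norm(fp$V %*% t(fp$V) - Ap, "F")
    expect_lt(err, 1e-7) # reconstruction error controlled by clamped mass
    expect_error(approxFactorize(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("cut objective counts crossing weight and is sign-symmetric", {
    w <- 0.73
    W <- matrix(c(0, w, w, 0), 2)
    L <- graphLaplacian(W)
    expect_equal(cutObjective(c(1, -1), L), w)
    expect_equal(cutObjective(c(1, 1), L), 0)
    set.seed(6)
    W <- randomGraph(9)
    L <- graphLaplacian(W)
    s <- sign(rnorm(9))
    expect_equal(cutObjective(s, L), cutObjective(-s, L))
    expect_error(cutObjective(c(1, 0), matrix(0, 2, 2)), "\\+1 or -1")
})

test_that("brute force enumerates the exact optimum", {
    W1 <- matrix(c(0, 1, 1, 0), 2)
    expect_equal(bruteForceMaxCut(W1)$opt, 1)
    W3 <- matrix(1, 3, 3)
    diag(W3) <- 0
    expect_equal(bruteForceMaxCut(W3)$opt, 2) # any 2-1 split of C3
    W4 <- matrix(0, 4, 4) # 4-cycle: alternating cut takes all 4 edges
    W4[cbind(1:4, c(2, 3, 4, 1))] <- 1
    W4 <- pmax(W4, t(W4))
    res <- bruteForceMaxCut(W4)
    expect_equal(res$opt, 4)
    expect_equal(cutObjective(res$s, graphLaplacian(W4)), 4)
    # permuting nodes leaves the optimum unchanged
    set.seed(7)
    W <- randomGraph(8)
    perm <- sample(8)
    expect_equal(bruteForceMaxCut(W[perm, perm])$opt,
        bruteForceMaxCut(W)$opt)
    expect_error(bruteForceMaxCut(diag(0, 23)), "n > 22")
})

test_that("rounding is exact on antipodal embeddings, optimal on the triangle", {
    L <- matrix(c(1, -1, -1, 1), 2)
    V <- rbind(c(1, 0), c(-1, 0)) # antipodal unit vectors
    cut <- roundHyperplane(V, L, sdpBound = 1, seed = 1)
    expect_equal(cut@objective, 1)
    expect_equal(cut@nRounds, 1L)
    # triangle: best of 100 draws reaches the true OPT = 2,
    # ratio 2/2.25 ~ 0.889 >= 0.878
    W <- matrix(1, 3, 3)
    diag(W) <- 0
    L3 <- graphLaplacian(W)
    sol <- solveSdp(L3)
    V3 <- approxFactorize(sol@A)$V
    cut3 <- roundHyperplane(V3, L3, sdpBound = sol@sdpBound,
        thresholdRatio = 1, maxRounds = 100, seed = 2)
    expect_equal(cut3@objective, 2, tolerance = 1e-6)
    expect_gte(cut3@objective / sol@sdpBound, 0.878)
})

test_that("rounding is deterministic under a seed and warns when capped", {
    set.seed(8)
    L <- graphLaplacian(randomGraph(10))
    sol <- solveSdp(L)
    V <- approxFactorize(sol@A)$V
    c1 <- roundHyperplane(V, L, sol@sdpBound, seed = 33)
    c2 <- roundHyperplane(V, L, sol@sdpBound, seed = 33)
    expect_identical(c1@s, c2@s)
    expect_identical(c1@nRounds, c2@nRounds)
    # unreachable threshold: returns best-so-far with a warning
    expect_warning(
        capped <- roundHyperplane(V, L, sdpBound = 10 * sol@sdpBound,
            thresholdRatio = 0.99, maxRounds = 8, seed = 1),
        "exhausted")
    expect_equal(capped@nRounds, 8L)
    expect_true(all(capped@s %in% c(-1, 1)))
})

test_that("weak duality and near-oracle rounding hold on random graphs", {
    set.seed(9)
    hits <- 0L
    for (i in 1:10) {
        n <- sample(8:10, 1)
        W <- randomGraph(n)
        L <- graphLaplacian(W)
        opt <- bruteForceMaxCut(W)$opt
        sol <- solveSdp(L)
        expect_gte(sol@sdpBound + 1e-6, opt) # relaxation bounds OPT
        V <- approxFactorize(sol@A)$V
        cut <- roundHyperplane(V, L, sol@sdpBound, thresholdRatio = 1,
            maxRounds = 300, seed = i)
        expect_lte(cut@objective, sol@sdpBound + 1e-6) # weak duality
        expect_gte(cut@objective, 0.878 * opt)
        if (abs(cut@objective - opt) < 1e-9) hits <- hits + 1L
    }
    expect_gte(hits, 8L)
})
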
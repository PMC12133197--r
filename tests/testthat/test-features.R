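test_that("radial position scales by the nuclear radius", {
    expect_equal(radialPosition(matrix(0, 1, 3)), 0)
    expect_equal(radialPosition(matrix(c(0, 0, 5000), 1)), 1)
    # 3-4-5 triangle at the 5 um default
    expect_equal(radialPosition(matrix(c(3000, 4000, 0), 1)), 1)
})

test_that("radial variability is log2 of sigma against the chromosome mean", {
    R <- rbind(c(0.2, 0.4, 0.6), c(0.4, 0.6, 0.8)) # equal spread per bin
    expect_equal(radialVariability(R), c(0, 0, 0))
    # doubling one bin's spread raises only that bin, recomputed directly
    R2 <- rbind(c(0.2, 0.4, 0.6), c(0.4, 0.6, 1.0))
    sig <- apply(R2, 2, function(v) sqrt(mean((v - mean(v))^2)))
    expect_equal(radialVariability(R2), log2(sig / mean(sig)))
    expect_gt(radialVariability(R2)[3], 0)
    expect_lt(radialVariability(R2)[1], 0)
    expect_error(radialVariability(rbind(c(1, 1), c(1, 1))), "zero")
})

test_that("radius of gyration matches the closed form and is rigid-invariant", {
    expect_equal(radiusOfGyration(matrix(1, 5, 3)), rep(0, 5))
    co <- rbind(c(-2, 0, 0), c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0),
        c(2, 0, 0))
    # centre of mass at origin, mean squared distance (4+1+0+1+4)/5 = 2
    expect_equal(radiusOfGyration(co)[3], sqrt(2))
    set.seed(11)
    X <- matrix(rnorm(30, sd = 100), 10, 3)
    th <- 0.7
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    expect_equal(radiusOfGyration(X %*% t(Rz) + 50),
        radiusOfGyration(X), tolerance = 1e-9)
})

test_that("interchromosomal contacts count foreign beads within range", {
    trA <- makeTrace(matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE))
    trB <- makeTrace(matrix(c(5000, 0, 0, 6000, 0, 0), 2, 3, byrow = TRUE),
        cellId = "c1b")
    cnt <- interchromContacts(list(trA, trB))
    expect_equal(cnt[[1]], c(0L, 0L)) # separated by > 1 um
    trC <- makeTrace(matrix(c(999, 0, 0, 4000, 0, 0), 2, 3, byrow = TRUE))
    cnt2 <- interchromContacts(list(trA, trC))
    expect_equal(cnt2[[1]][1], 1L) # boundary bead at 999 nm counts
    # total count is symmetric between the two chromosomes
    expect_equal(sum(cnt2[[1]]), sum(cnt2[[2]]))
    expect_error(interchromContacts(list(trA)), "two chromosomes")
})

test_that("contact score is the intra fraction of contacts", {
    co <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(5000, 0, 0))
    expect_equal(contactScore(co, c(1, 1, 1, 1), rBead = 100), 1)
    # 3 beads pairwise in contact: labels (1,1,0) give 1 intra + 2 inter
    co3 <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
    expect_equal(contactScore(co3, c(1, 1, 0), rBead = 100), 1 / 3)
    # 3 intra + 1 inter contacts -> 0.75
    co4 <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(0, 290, 0))
    expect_equal(contactScore(co4, c(1, 1, 1, 0), rBead = 100), 0.75)
    expect_true(is.na(contactScore(co, c(1, 0, 1, 0), rBead = 1e-3)))
})

test_that("distance score is the intra share of summed distances", {
    # two tight clusters, correct labels: intra share well below 0.5
    cl <- rbind(c(0, 0, 0), c(10, 0, 0), c(3000, 0, 0), c(3010, 0, 0))
    lab <- c(1, 1, 0, 0)
    sd1 <- distanceScore(cl, lab)
    D <- as.matrix(dist(cl))
    dIntra <- D[1, 2] + D[3, 4]
    dInter <- D[1, 3] + D[1, 4] + D[2, 3] + D[2, 4]
    expect_equal(sd1, dIntra / (dIntra + dInter))
    expect_lt(sd1, 0.5)
    expect_equal(distanceScore(cl, 1 - lab), sd1) # label-swap symmetric
    expect_true(is.na(distanceScore(matrix(0, 4, 3), lab))) # 0/0
    expect_true(is.na(distanceScore(cl, c(1, 1, 1, 1)))) # one side empty
})

test_that("speckle variability is the across-cell population sd", {
    spd <- rbind(c(100, 500), c(300, 500))
    expect_equal(speckleVariability(spd), c(100, 0))
    expect_equal(speckleVariability(spd[2:1, ]), c(100, 0))
})

test_that("planted labels out-score permuted labels on structured cells", {
    set.seed(12)
    sim <- simulatePopulation(syntheticConfig(nLoci = 30, nCells = 5,
        labelNoise = 0, seed = 13))
    sc <- vapply(traces(sim$population), function(tr)
        contactScore(tr@coords, sim$truth, rBead = 200), numeric(1))
    dsc <- vapply(traces(sim$population), function(tr)
        distanceScore(tr@coords, sim$truth), numeric(1))
    perm <- sample(sim$truth)
    scP <- vapply(traces(sim$population), function(tr)
        contactScore(tr@coords, perm, rBead = 200), numeric(1))
    dscP <- vapply(traces(sim$population), function(tr)
        distanceScore(tr@coords, perm), numeric(1))
    expect_gt(mean(sc), mean(scP))
    expect_lt(mean(dsc), mean(dscP))
    expect_true(all(c(sc, scP, dsc, dscP) >= 0 & c(sc, scP, dsc, dscP) <= 1))
})
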
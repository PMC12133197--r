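test_that("the speckle-proximal side becomes A, regardless of cut sign", {
    cut <- new("CutSolution", s = c(1, 1, -1), objective = 1,
        sdpBound = 1, nRounds = 1L, thresholdRatio = 0.878,
        seed = NA_integer_)
    p <- assignAB(cut, c(100, 120, 400))
    expect_equal(calls(p), c(1L, 1L, 0L))
    cutFlip <- cut
    cutFlip@s <- -cut@s
    expect_equal(calls(assignAB(cutFlip, c(100, 120, 400))), calls(p))
    # exact tie: the side containing the first node is A
    expect_message(
        pt <- assignAB(cut, c(100, 300, 200)),
        "tie")
    expect_equal(calls(pt), c(1L, 1L, 0L))
    # a trivial partition is an error
    cutDeg <- cut
    cutDeg@s <- c(1, 1, 1)
    expect_error(assignAB(cutDeg, c(1, 2, 3)), "degenerate")
})

test_that("ensemble vector averages profiles and ignores cell order", {
    p1 <- makeProfile(c(1, 0))
    p2 <- makeProfile(c(1, 1), "c2")
    expect_equal(ensembleVector(list(p1, p2)), c(1, 0.5))
    expect_equal(ensembleVector(list(p2, p1)), c(1, 0.5))
    expect_equal(ensembleVector(list(p1, p1, p1)), c(1, 0))
})

test_that("frequency formulas match their printed definitions", {
    expect_equal(compartmentFrequency(0.8), 0.8)
    expect_equal(compartmentFrequency(0.3), -0.7)
    expect_equal(compartmentFrequency(0.5), 0.5) # strict < in the indicator
    expect_equal(normalizedFrequency(c(0.5, 1, 0)), c(0, 0.5, -0.5))
    cEns <- seq(0, 1, by = 0.125)
    expect_true(all(abs(compartmentFrequency(cEns)) >= 0.5))
    expect_equal(mean(normalizedFrequency(cEns)), mean(cEns) - 0.5)
})

test_that("variability is the population sd and obeys the Bernoulli identity", {
    agree <- list(makeProfile(c(1, 0)), makeProfile(c(1, 0), "c2"))
    expect_equal(compartmentVariability(agree), c(0, 0))
    split <- list(makeProfile(c(1, 1)), makeProfile(c(0, 0), "c2"))
    expect_equal(compartmentVariability(split), c(0.5, 0.5))
    set.seed(10)
    profs <- lapply(1:7, function(k)
        makeProfile(rbinom(9, 1, 0.4), sprintf("c%d", k)))
    dc <- compartmentVariability(profs)
    ce <- ensembleVector(profs)
    expect_equal(dc, sqrt(ce * (1 - ce)), tolerance = 1e-12)
    ens <- ensembleCompartments(profs, makeTrace(matrix(0, 9, 3))@panel)
    expect_true(validObject(ens))
})

test_that("transcription ratio groups by both homologs and drops bottom 5%", {
    # 100 cells, two homologs each; gene at bin 0; cells 1..50 both-A,
    # 51..100 both-B; counts 1..100 so the filter drops counts 1..5
    profs <- unlist(lapply(1:100, function(k) {
        lab <- if (k <= 50) 1L else 0L
        list(makeProfile(c(lab, 0L), sprintf("c%03d", k), "1"),
            makeProfile(c(lab, 0L), sprintf("c%03d", k), "2"))
    }), recursive = FALSE)
    counts <- data.frame(cell_id = sprintf("c%03d", 1:100), gene = "g1",
        count = 1:100)
    tab <- transcriptionRatio(profs, counts, data.frame(gene = "g1", bin = 0L))
    expect_equal(tab$n_A + tab$n_B, 95L) # bottom 5 of 100 removed
    expect_equal(tab$n_A, 45L) # dropped counts 1..5 were all A cells
    expect_equal(tab$t_A, mean(6:50))
    expect_equal(tab$t_B, mean(51:100))
    expect_equal(tab$trans, log2(mean(6:50) / mean(51:100)))
    # simple ratios
    profs2 <- list(makeProfile(1L, "a", "1"), makeProfile(1L, "a", "2"),
        makeProfile(0L, "b", "1"), makeProfile(0L, "b", "2"))
    counts2 <- data.frame(cell_id = c("a", "b"), gene = "g",
        count = c(4, 2))
    tab2 <- transcriptionRatio(profs2, counts2,
        data.frame(gene = "g", bin = 0L), bottomFrac = 0)
    expect_equal(tab2$trans, 1) # log2(4/2)
    # empty group reported as NA, not 0
    counts3 <- data.frame(cell_id = c("a", "b"), gene = "g", count = c(4, 4))
    profs3 <- list(makeProfile(1L, "a", "1"), makeProfile(1L, "a", "2"),
        makeProfile(1L, "b", "1"), makeProfile(1L, "b", "2"))
    tab3 <- transcriptionRatio(profs3, counts3,
        data.frame(gene = "g", bin = 0L), bottomFrac = 0)
    expect_true(is.na(tab3$trans))
    # unmappable gene is skipped with a warning
    expect_warning(
        out <- transcriptionRatio(profs2, counts2,
            data.frame(gene = "g", bin = 99L), bottomFrac = 0),
        "does not map")
    expect_null(out)
})
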
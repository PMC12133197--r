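test_that("simple dialect parses cells, keeps missing loci, sorts bins", {
    lines <- c(
        "cell_id,chrom,bin_start,bin_end,x,y,z,speckle_dist",
        "c1,chr1,200000,400000,10,20,30,150",
        "c1,chr1,0,200000,1,2,3,100",
        "c1,chr1,400000,600000,,8,9,200",
        "c2,chr1,0,200000,4,5,6,110",
        "c2,chr1,200000,400000,7,8,9,120",
        "c2,chr1,400000,600000,10,11,12,130")
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    tp <- readTraces(f)
    expect_equal(nCells(tp), 2)
    expect_equal(nLoci(tp), 3)
    tr1 <- traces(tp)[[1]]
    # out-of-order rows re-sorted ascending by bin_start
    expect_equal(GenomicRanges::start(tracePanel(tr1)) - 1L,
        c(0L, 200000L, 400000L))
    expect_equal(tr1@coords[, 1], c(1, 10, NA))
    # empty X field recorded as missing, locus kept
    expect_true(is.na(tr1@coords[3, 1]) && !is.na(tr1@coords[3, 2]))
    expect_equal(speckleDist(tr1), c(100, 150, 200))
})

test_that("missing required columns and panel mismatches are errors", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("cell_id,chrom,bin_start,bin_end,x,y",
        "c1,chr1,0,200000,1,2"), f)
    expect_error(readTraces(f), "z")
    f2 <- tempfile(fileext = ".csv")
    writeLines(c("cell_id,chrom,bin_start,bin_end,x,y,z",
        "c1,chr1,0,200000,1,2,3",
        "c1,chr1,200000,400000,1,2,3",
        "c2,chr1,0,100000,1,2,3",
        "c2,chr1,100000,200000,1,2,3"), f2)
    expect_error(readTraces(f2), "panel mismatch")
})

test_that("fofct dialect honors the columns header and unit metadata", {
    lines <- c("##FOF-CT_version=v0.1",
        "##XYZ_unit=micron",
        "##columns=(Trace_ID, X, Y, Z, Chrom, Chrom_Start, Chrom_End)",
        "t1,0.1,0.2,0.3,chr1,0,1000000",
        "t1,0.4,0.5,0.6,chr1,1000000,2000000")
    f <- tempfile(fileext = ".csv")
    writeLines(lines, f)
    tp <- readTraces(f, dialect = "fofct")
    expect_equal(traces(tp)[[1]]@coords[1, ], c(x = 100, y = 200, z = 300))
    bad <- tempfile()
    writeLines(c("##columns=(Trace_ID, X, Y, Chrom)", "t1,1,2,chr1"), bad)
    expect_error(readTraces(bad, dialect = "fofct"), "Chrom_Start")
})

test_that("parse -> write -> parse is idempotent on the simple dialect", {
    sim <- simulatePopulation(syntheticConfig(nLoci = 8, nCells = 3,
        seed = 11))
    f1 <- tempfile(fileext = ".csv")
    f2 <- tempfile(fileext = ".csv")
    writeTraces(sim$population, f1)
    tp1 <- readTraces(f1)
    writeTraces(tp1, f2)
    tp2 <- readTraces(f2)
    expect_equal(length(traces(tp1)), length(traces(tp2)))
    for (i in seq_along(traces(tp1))) {
        expect_equal(traces(tp1)[[i]]@coords, traces(tp2)[[i]]@coords)
        expect_equal(speckleDist(traces(tp1)[[i]]),
            speckleDist(traces(tp2)[[i]]))
    }
})

test_that("interpolation fills interior gaps linearly and copies at ends", {
    co <- matrix(rep(c(0, NA, 10), 3), ncol = 3)
    tr <- makeTrace(co)
    out <- interpolateMissing(tr)
    expect_equal(unname(out@coords[2, ]), c(5, 5, 5)) # midpoint
    # closed-form interior fill: observed 0 and 8 at indices 0 and 4
    co2 <- matrix(NA_real_, 5, 3)
    co2[1, ] <- 0
    co2[5, ] <- 8
    expect_equal(interpolateMissing(makeTrace(co2))@coords[, 2],
        c(0, 2, 4, 6, 8))
    # leading gap copies the first observed value
    co3 <- matrix(c(NA, 3, 6), 3, 3)
    expect_equal(interpolateMissing(makeTrace(co3))@coords[1, 1], 3)
    # speckle values interpolate alongside coordinates
    tr4 <- makeTrace(matrix(1, 3, 3) * c(1, 2, 3),
        speckleDist = c(100, NA, 300))
    expect_equal(interpolateMissing(tr4)@speckleDist, c(100, 200, 300))
})

test_that("interpolation is identity on complete traces, rejects sparse ones", {
    co <- matrix(rnorm(15), 5, 3)
    tr <- makeTrace(co)
    expect_identical(interpolateMissing(tr)@coords, tr@coords)
    co[2:5, ] <- NA
    expect_error(interpolateMissing(makeTrace(co)), "fewer than 2")
})

test_that("ensemble bedGraph round-trips and BED9 colors A red, B blue", {
    profs <- list(makeProfile(c(1, 0, 1)), makeProfile(c(1, 0, 0), "c2"),
        makeProfile(c(1, 1, 0), "c3"))
    panel <- makeTrace(matrix(0, 3, 3))@panel
    ens <- ensembleCompartments(profs, panel)
    bg <- tempfile(fileext = ".bedgraph")
    writeEnsembleBedGraph(ens, bg)
    back <- rtracklayer::import(bg, format = "bedGraph")
    expect_equal(back$score, ens@fNorm, tolerance = 1e-6)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(panel))
    bed <- rtracklayer::import(sub("bedgraph$", "bed", bg))
    expect_equal(bed$itemRgb,
        ifelse(cEns(ens) >= 0.5, "#FF0000", "#0000FF"))
    # empty ensemble errors instead of writing an empty file
    empty <- new("EnsembleCompartments", panel = GenomicRanges::GRanges(),
        cEns = numeric(0), f = numeric(0), fNorm = numeric(0),
        deltaC = numeric(0), K = 0L)
    expect_error(writeEnsembleBedGraph(empty, tempfile()), "empty")
})

test_that("per-cell call CSV round-trips", {
    profs <- list(makeProfile(c(1, 0, 1), "cellA", "1"),
        makeProfile(c(0, 0, 1), "cellA", "2"))
    panel <- makeTrace(matrix(0, 3, 3))@panel
    f <- tempfile(fileext = ".csv")
    writeCalls(profs, panel, f)
    back <- readCalls(f)
    expect_equal(length(back), 2)
    expect_equal(calls(back[[1]]), c(1L, 0L, 1L))
    expect_equal(homolog(back[[2]]), "2")
})

test_that("CG track maps onto the panel by overlap", {
    panel <- makeTrace(matrix(0, 3, 3))@panel
    f <- tempfile(fileext = ".bedgraph")
    writeLines(c("chrT\t0\t200000\t0.55",
        "chrT\t200000\t400000\t0.40",
        "chrT\t400000\t600000\t0.61"), f)
    expect_equal(readCgTrack(f, panel), c(0.55, 0.40, 0.61))
})
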
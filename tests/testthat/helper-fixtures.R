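# Fixtures shared across test files; everything is built in code.

# A bare trace on an evenly spaced panel, coordinates and speckle
# distances supplied by the caller.
makeTrace <- function(coords, speckleDist = numeric(0),
                      speckleIntensity = numeric(0),
                      laminaDist = numeric(0), cellId = "c1",
                      homolog = "1", binIndex = NULL,
                      resolution = 2e5) {
    n <- nrow(coords)
    if (is.null(binIndex)) binIndex <- seq_len(n) - 1L
    panel <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(start = binIndex * resolution + 1L,
            width = resolution))
    panel$binIndex <- as.integer(binIndex)
    new("ChromatinTrace", cellId = cellId, homolog = homolog,
        panel = panel, coords = coords, speckleDist = speckleDist,
        speckleIntensity = speckleIntensity, laminaDist = laminaDist)
}

makeProfile <- function(calls, cellId = "c1", homolog = "1") {
    new("CompartmentProfile", cellId = cellId, homolog = homolog,
        calls = as.integer(calls))
}

# Random complete graph with uniform(0, 1) weights.
randomGraph <- function(n) {
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2)
    W + t(W)
}

graphLaplacian <- function(W) diag(rowSums(W)) - W

# Deterministic two-cluster population: half the bins sit in a tight
# cluster near the origin, half in a tight cluster `sep` nm away, with
# per-bin deterministic offsets so rows are not identical. Cluster-1
# bins get small speckle distances.
twoBlockPopulation <- function(nBins = 12, nCellsPop = 3, sep = 3000) {
    half <- nBins %/% 2
    labels <- c(rep(1L, half), rep(0L, nBins - half))
    trs <- lapply(seq_len(nCellsPop), function(k) {
        off <- (seq_len(nBins) - 1) * 40 + (k - 1) * 15
        coords <- cbind(ifelse(labels == 1L, 0, sep) + off,
            (seq_len(nBins) %% 3) * 30, 0)
        spd <- ifelse(labels == 1L, 100, 2000) + off / 10
        makeTrace(coords, speckleDist = spd,
            cellId = sprintf("c%d", k))
    })
    panel <- trs[[1]]@panel
    list(pop = new("TracePopulation", panel = panel, traces = trs,
        resolution = 2e5), labels = labels)
}
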
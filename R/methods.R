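#' Accessors for scMaxCut classes
#'
#' Accessor generics for the package's S4 containers: trace and
#' population metadata, graph matrices, cut labels and ensemble vectors.
#'
#' @param x an scMaxCut object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("cellId", "ChromatinTrace", function(x) x@cellId)
#' @rdname accessors
setMethod("homolog", "ChromatinTrace", function(x) x@homolog)
#' @rdname accessors
setMethod("tracePanel", "ChromatinTrace", function(x) x@panel)
#' @rdname accessors
setMethod("tracePanel", "TracePopulation", function(x) x@panel)
#' @rdname accessors
setMethod("tracePanel", "EnsembleCompartments", function(x) x@panel)
#' @rdname accessors
setMethod("traceCoords", "ChromatinTrace", function(x) x@coords)
#' @rdname accessors
setMethod("speckleDist", "ChromatinTrace", function(x) x@speckleDist)
#' @rdname accessors
setMethod("laminaDist", "ChromatinTrace", function(x) x@laminaDist)
#' @rdname accessors
setMethod("nLoci", "ChromatinTrace", function(x) length(x@panel))
#' @rdname accessors
setMethod("nLoci", "TracePopulation", function(x) length(x@panel))
#' @rdname accessors
setMethod("nCells", "TracePopulation",
    function(x) length(unique(vapply(x@traces, cellId, character(1)))))
#' @rdname accessors
setMethod("traces", "TracePopulation", function(x) x@traces)
#' @rdname accessors
setMethod("adjacency", "StructureGraph", function(x) x@W)
#' @rdname accessors
setMethod("laplacian", "StructureGraph", function(x) x@laplacian)
#' @rdname accessors
setMethod("speckleZ", "StructureGraph", function(x) x@speckleZ)
#' @rdname accessors
setMethod("calls", "CompartmentProfile", function(x) x@calls)
#' @rdname accessors
setMethod("cellId", "CompartmentProfile", function(x) x@cellId)
#' @rdname accessors
setMethod("homolog", "CompartmentProfile", function(x) x@homolog)
#' @rdname accessors
setMethod("cEns", "EnsembleCompartments", function(x) x@cEns)
#' @rdname accessors
setMethod("cutLabels", "CutSolution", function(x) x@s)
#' @rdname accessors
setMethod("cutValue", "CutSolution", function(x) x@objective)
#' @rdname accessors
setMethod("sdpBound", "CutSolution", function(x) x@sdpBound)
#' @rdname accessors
setMethod("sdpBound", "SdpSolution", function(x) x@sdpBound)

#' @rdname accessors
setMethod("length", "ChromatinTrace", function(x) length(x@panel))

setMethod("show", "ChromatinTrace", function(object) {
    n <- length(object@panel)
    chrom <- as.character(GenomicRanges::seqnames(object@panel)[1])
    nmiss <- sum(!stats::complete.cases(object@coords))
    cat("ChromatinTrace:", object@cellId,
        sprintf("(homolog %s)", object@homolog), "\n")
    cat(" ", chrom, "with", n, "loci;", nmiss, "missing\n")
    cat("  speckle info:",
        if (length(object@speckleDist)) "distances"
        else if (length(object@speckleIntensity)) "intensities"
        else "none", "\n")
})

setMethod("show", "TracePopulation", function(object) {
    cat("TracePopulation:", length(object@traces), "traces,",
        nCells(object), "cells,", length(object@panel), "loci at",
        object@resolution / 1e3, "kb resolution\n")
})

setMethod("show", "StructureGraph", function(object) {
    cat("StructureGraph with", object@n, "nodes,",
        object@keptEdges, "edges kept after pruning\n")
})

setMethod("show", "CutSolution", function(object) {
    cat("CutSolution:", length(object@s), "nodes; cut value",
        signif(object@objective, 6), "of SDP bound",
        signif(object@sdpBound, 6),
        sprintf("(ratio %.3f) after %d draws\n",
            object@objective / max(object@sdpBound, .Machine$double.eps),
            object@nRounds))
})

setMethod("show", "EnsembleCompartments", function(object) {
    cat("EnsembleCompartments over K =", object@K, "cells,",
        length(object@cEns), "bins;",
        sum(object@cEns >= 0.5), "majority-A,",
        sum(object@cEns < 0.5), "majority-B\n")
})

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nLoci, "loci x", object@nCells,
        "cells x", object@nHomologs, "homolog(s); pull", object@pull,
        "separation", object@separation, "nm; seed", object@seed, "\n")
})
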
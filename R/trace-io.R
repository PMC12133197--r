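#' Read single-cell chromosome trace tables
#'
#' Reads per-cell chromatin trace tables into a
#' \linkS4class{TracePopulation}. Two dialects are supported:
#' \describe{
#'   \item{\code{simple}}{a headed CSV/TSV with columns \code{cell_id},
#'     \code{chrom}, \code{bin_start}, \code{bin_end}, \code{x},
#'     \code{y}, \code{z} and optionally \code{homolog},
#'     \code{speckle_dist}, \code{speckle_intensity},
#'     \code{lamina_dist}.}
#'   \item{\code{fofct}}{a chromatin-trace CSV in the style of the
#'     FISH-omics trace exchange tables: \code{##}-prefixed metadata
#'     lines, one of which is
#'     \code{##columns=(Trace_ID, X, Y, Z, Chrom, Chrom_Start,
#'     Chrom_End, ...)}, followed by unheaded data rows.}
#' }
#' Genomic intervals are 0-based half-open. Coordinates are stored in
#' nanometres; a metadata/comment line declaring micrometre units
#' (e.g. \code{#units=um} or \code{##XYZ_unit=micron}) triggers
#' conversion. Unparseable or empty coordinate fields are recorded as
#' missing (the locus is kept); loci are sorted by \code{bin_start}
#' within each trace. One trace is created per (cell, chromosome,
#' homolog) combination; homologs are never merged.
#'
#' @param path path to the trace table.
#' @param dialect \code{"simple"} (default) or \code{"fofct"}.
#' @param resolution bin size in bp; inferred from the modal bin width
#'   when \code{NULL}.
#' @return A \linkS4class{TracePopulation}. All traces share one locus
#'   panel; a trace whose bins disagree with it is an error.
#' @examples
#' tp <- simulatePopulation(syntheticConfig(nLoci = 10, nCells = 2))$population
#' f <- tempfile(fileext = ".csv")
#' writeTraces(tp, f)
#' readTraces(f)
#' @export
readTraces <- function(path, dialect = c("simple", "fofct"),
                       resolution = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "simple") {
        tab <- .readSimple(path)
    } else {
        tab <- .readFofct(path)
    }
    .populationFromTable(tab, resolution)
}

.unitFactor <- function(lines) {
    um <- grepl("unit[s]?\\s*[:=]?\\s*(um|µm|micron|micrometer)",
        lines, ignore.case = TRUE)
    if (any(um)) 1000 else 1
}

.numOrNA <- function(x) suppressWarnings(as.numeric(x))

.readSimple <- function(path) {
    first <- readLines(path, n = 20L)
    comments <- first[startsWith(first, "#")]
    fac <- .unitFactor(comments)
    tab <- data.table::fread(path, header = TRUE, sep = "auto",
        colClasses = "character", skip = length(comments),
        data.table = TRUE, showProgress = FALSE)
    req <- c("cell_id", "chrom", "bin_start", "bin_end", "x", "y", "z")
    miss <- setdiff(req, names(tab))
    if (length(miss))
        stop("trace table is missing required column(s): ",
            paste(miss, collapse = ", "))
    out <- data.table::data.table(
        cell_id = tab$cell_id,
        homolog = if ("homolog" %in% names(tab)) tab$homolog else "1",
        chrom = tab$chrom,
        bin_start = as.integer(tab$bin_start),
        bin_end = as.integer(tab$bin_end),
        x = .numOrNA(tab$x) * fac,
        y = .numOrNA(tab$y) * fac,
        z = .numOrNA(tab$z) * fac
    )
    for (col in c("speckle_dist", "speckle_intensity", "lamina_dist")) {
        if (col %in% names(tab)) {
            v <- .numOrNA(tab[[col]])
            if (col != "speckle_intensity") v <- v * fac
            out[[col]] <- v
        }
    }
    out
}

.readFofct <- function(path) {
    lines <- readLines(path)
    meta <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
    colLine <- grep("columns\\s*=", meta, value = TRUE)
    if (!length(colLine))
        stop("fofct file lacks a '##columns=(...)' header line")
    cols <- sub(".*columns\\s*=\\s*\\(?", "", colLine[1])
    cols <- trimws(strsplit(gsub("[)\"]", "", cols), ",")[[1]])
    req <- c("Trace_ID", "Chrom", "Chrom_Start", "Chrom_End", "X", "Y", "Z")
    miss <- setdiff(req, cols)
    if (length(miss))
        stop("fofct header is missing required column(s): ",
            paste(miss, collapse = ", "))
    fac <- .unitFactor(meta)
    tab <- data.table::fread(text = body, header = FALSE,
        colClasses = "character", data.table = TRUE, showProgress = FALSE)
    if (ncol(tab) < length(cols))
        stop("fofct data rows have fewer fields than the columns header")
    data.table::setnames(tab, seq_along(cols), cols)
    out <- data.table::data.table(
        cell_id = tab$Trace_ID,
        homolog = if ("Homolog" %in% cols) tab$Homolog else "1",
        chrom = tab$Chrom,
        bin_start = as.integer(tab$Chrom_Start),
        bin_end = as.integer(tab$Chrom_End),
        x = .numOrNA(tab$X) * fac,
        y = .numOrNA(tab$Y) * fac,
        z = .numOrNA(tab$Z) * fac
    )
    if ("SpD" %in% cols) out$speckle_dist <- .numOrNA(tab$SpD) * fac
    if ("Speckle_Intensity" %in% cols)
        out$speckle_intensity <- .numOrNA(tab$Speckle_Intensity)
    if ("LmD" %in% cols) out$lamina_dist <- .numOrNA(tab$LmD) * fac
    out
}

.populationFromTable <- function(tab, resolution = NULL) {
    data.table::setorder(tab, cell_id, homolog, chrom, bin_start)
    key <- paste(tab$cell_id, tab$chrom, tab$homolog, sep = "\r")
    pieces <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
    panel <- NULL
    traceList <- vector("list", length(pieces))
    for (i in seq_along(pieces)) {
        rows <- tab[pieces[[i]], ]
        gr <- GenomicRanges::GRanges(rows$chrom,
            IRanges::IRanges(start = rows$bin_start + 1L, end = rows$bin_end))
        gr$binIndex <- seq_along(gr) - 1L
        if (is.null(panel)) {
            panel <- gr
        } else if (length(gr) != length(panel) ||
            any(GenomicRanges::start(gr) != GenomicRanges::start(panel)) ||
            any(as.character(GenomicRanges::seqnames(gr)) !=
                as.character(GenomicRanges::seqnames(panel)))) {
            stop("panel mismatch: trace ", rows$cell_id[1],
                " does not share the population locus panel")
        }
        traceList[[i]] <- new("ChromatinTrace",
            cellId = rows$cell_id[1],
            homolog = as.character(rows$homolog[1]),
            panel = gr,
            coords = cbind(x = rows$x, y = rows$y, z = rows$z),
            speckleDist = if ("speckle_dist" %in% names(rows))
                rows$speckle_dist else numeric(0),
            speckleIntensity = if ("speckle_intensity" %in% names(rows))
                rows$speckle_intensity else numeric(0),
            laminaDist = if ("lamina_dist" %in% names(rows))
                rows$lamina_dist else numeric(0))
    }
    if (is.null(resolution)) {
        w <- GenomicRanges::width(panel)
        resolution <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
    }
    new("TracePopulation", panel = panel, traces = traceList,
        resolution = resolution)
}

#' Write a trace population in the simple dialect
#'
#' Inverse of \code{readTraces(..., dialect = "simple")}; round-trips
#' losslessly up to numeric formatting.
#'
#' @param population a \linkS4class{TracePopulation}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeTraces <- function(population, path) {
    rows <- lapply(traces(population), function(tr) {
        n <- length(tr@panel)
        dt <- data.table::data.table(
            cell_id = rep(tr@cellId, n),
            homolog = rep(tr@homolog, n),
            chrom = as.character(GenomicRanges::seqnames(tr@panel)),
            bin_start = GenomicRanges::start(tr@panel) - 1L,
            bin_end = GenomicRanges::end(tr@panel),
            x = tr@coords[, 1], y = tr@coords[, 2], z = tr@coords[, 3])
        if (length(tr@speckleDist)) dt$speckle_dist <- tr@speckleDist
        if (length(tr@speckleIntensity))
            dt$speckle_intensity <- tr@speckleIntensity
        if (length(tr@laminaDist)) dt$lamina_dist <- tr@laminaDist
        dt
    })
    out <- data.table::rbindlist(rows, fill = TRUE)
    data.table::fwrite(out, path)
    invisible(path)
}

#' Fill missing trace values by linear interpolation
#'
#' Replaces missing coordinates (and missing speckle/lamina values) by
#' linear interpolation in bin index between flanking observed loci;
#' leading and trailing gaps take the nearest observed value, so no
#' extrapolation is performed. A locus counts as observed when all three
#' coordinates are present.
#'
#' @param trace a \linkS4class{ChromatinTrace}.
#' @return The trace with complete, finite coordinates.
#' @examples
#' tp <- simulatePopulation(syntheticConfig(nLoci = 8, nCells = 1))$population
#' tr <- traces(tp)[[1]]
#' tr@coords[3, ] <- NA
#' interpolateMissing(tr)@coords[3, ]
#' @export
interpolateMissing <- function(trace) {
    idx <- trace@panel$binIndex
    obs <- stats::complete.cases(trace@coords)
    if (sum(obs) < 2L)
        stop("cannot preprocess trace ", trace@cellId,
            ": fewer than 2 observed loci")
    fill <- function(v) {
        ok <- !is.na(v)
        if (all(ok)) return(v)
        if (sum(ok) == 0L) return(v)
        if (sum(ok) == 1L) return(rep(v[ok], length(v)))
        stats::approx(idx[ok], v[ok], xout = idx, rule = 2)$y
    }
    coords <- apply(trace@coords, 2, fill)
    out <- trace
    out@coords <- coords
    if (length(trace@speckleDist)) out@speckleDist <- fill(trace@speckleDist)
    if (length(trace@speckleIntensity))
        out@speckleIntensity <- fill(trace@speckleIntensity)
    if (length(trace@laminaDist)) out@laminaDist <- fill(trace@laminaDist)
    if (any(!is.finite(out@coords)))
        stop("trace ", trace@cellId, " has non-finite coordinates after ",
            "interpolation")
    out
}

#' Preprocess every trace of a population
#'
#' Applies [interpolateMissing()] to each trace; traces with fewer than
#' two observed loci are dropped with a warning.
#'
#' @param population a \linkS4class{TracePopulation}.
#' @return The preprocessed population.
#' @export
preprocessPopulation <- function(population) {
    out <- lapply(traces(population), function(tr) {
        tryCatch(interpolateMissing(tr), error = function(e) {
            warning(conditionMessage(e), call. = FALSE)
            NULL
        })
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) stop("no usable traces after preprocessing")
    new("TracePopulation", panel = population@panel, traces = out,
        resolution = population@resolution)
}

.panelGRanges <- function(ens, score) {
    gr <- ens@panel
    S4Vectors::mcols(gr) <- NULL
    gr$score <- score
    gr
}

#' Write ensemble compartment tracks
#'
#' Writes a 4-column bedGraph (0-based half-open) of an ensemble
#' statistic, plus a companion BED9 file coloring majority-A bins red
#' (255,0,0) and majority-B bins blue (0,0,255).
#'
#' @param ens an \linkS4class{EnsembleCompartments}.
#' @param path output bedGraph path.
#' @param track which statistic to write: normalized frequency
#'   (\code{"fnorm"}, default), signed frequency (\code{"f"}), ensemble
#'   vector (\code{"cens"}) or variability (\code{"deltac"}).
#' @param bedPath path for the BED9 companion; default replaces the
#'   extension with \code{.bed}. \code{NA} suppresses it.
#' @return \code{path}, invisibly.
#' @export
writeEnsembleBedGraph <- function(ens, path,
                                  track = c("fnorm", "f", "cens", "deltac"),
                                  bedPath = NULL) {
    track <- match.arg(track)
    if (length(ens@cEns) == 0L)
        stop("empty ensemble: nothing to write")
    score <- switch(track, fnorm = ens@fNorm, f = ens@f, cens = ens@cEns,
        deltac = ens@deltaC)
    gr <- .panelGRanges(ens, score)
    rtracklayer::export(gr, path, format = "bedGraph")
    if (is.null(bedPath))
        bedPath <- paste0(tools::file_path_sans_ext(path), ".bed")
    if (!is.na(bedPath)) {
        isA <- ens@cEns >= 0.5
        bed <- .panelGRanges(ens, 0L)
        bed$score <- NULL
        bed$name <- ifelse(isA, "A", "B")
        bed$score <- 0L
        bed$itemRgb <- ifelse(isA, "#FF0000", "#0000FF")
        rtracklayer::export(bed, bedPath, format = "BED")
    }
    invisible(path)
}

#' Write per-cell compartment calls as a long CSV
#'
#' One row per (cell, homolog, bin) with the A/B label.
#'
#' @param profiles list of \linkS4class{CompartmentProfile}.
#' @param panel the shared locus panel (\code{GRanges}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(profiles, panel, path) {
    n <- length(panel)
    rows <- lapply(profiles, function(p) data.table::data.table(
        cell_id = rep(p@cellId, n),
        homolog = rep(p@homolog, n),
        chrom = as.character(GenomicRanges::seqnames(panel)),
        bin_start = GenomicRanges::start(panel) - 1L,
        bin_end = GenomicRanges::end(panel),
        label = ifelse(p@calls == 1L, "A", "B")))
    data.table::fwrite(data.table::rbindlist(rows), path)
    invisible(path)
}

#' Read per-cell calls written by [writeCalls()]
#'
#' @param path CSV path.
#' @return list of \linkS4class{CompartmentProfile}.
#' @export
readCalls <- function(path) {
    first <- readLines(path, n = 20L)
    tab <- data.table::fread(path, showProgress = FALSE,
        skip = sum(startsWith(first, "#")))
    key <- paste(tab$cell_id, tab$homolog, sep = "\r")
    lapply(split(tab, factor(key, levels = unique(key))), function(d) {
        d <- d[order(d$bin_start), ]
        new("CompartmentProfile", cellId = as.character(d$cell_id[1]),
            homolog = as.character(d$homolog[1]),
            calls = as.integer(d$label == "A"))
    })
}

#' Read a CG-content track
#'
#' Reads a bedGraph of per-bin CG fraction and maps it onto a locus
#' panel by overlap; uncovered bins take the nearest covered value (with
#' a warning).
#'
#' @param path bedGraph path.
#' @param panel locus panel \code{GRanges}.
#' @return numeric vector of CG fractions, one per panel bin.
#' @export
readCgTrack <- function(path, panel) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    hit <- GenomicRanges::findOverlaps(panel, gr, select = "first")
    cg <- gr$score[hit]
    if (anyNA(cg)) {
        warning(sum(is.na(cg)), " panel bin(s) uncovered by the CG track; ",
            "filled from the nearest covered bin")
        near <- GenomicRanges::nearest(panel, gr)
        cg[is.na(cg)] <- gr$score[near[is.na(cg)]]
    }
    if (any(cg < 0 | cg > 1))
        stop("CG content must lie in [0, 1]")
    as.numeric(cg)
}
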
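#' Call single-cell compartments for a whole population
#'
#' Runs the full per-trace pipeline — graph construction, semidefinite
#' relaxation, factorization, randomized rounding, speckle-oriented A/B
#' assignment — on every trace of a population. Failures are isolated:
#' a degenerate or unsolvable trace is skipped with a warning and
#' recorded in the diagnostics, so one bad cell never aborts a
#' population run.
#'
#' @param population a \linkS4class{TracePopulation} (preprocessed, or
#'   raw with \code{preprocess = TRUE}).
#' @param rBead bead radius in nm (100 for imaging data; modeled and
#'   synthetic structures need an explicit value, e.g. 200).
#' @param pruneFactor,gapMode,epsilonZ passed to [buildGraph()].
#' @param tolerance,thresholdRatio,maxRounds passed to [solveSdp()] and
#'   [roundHyperplane()].
#' @param seed integer master seed; trace i rounds with seed
#'   \code{seed + i}.
#' @param preprocess interpolate missing values first (default TRUE).
#' @param verbose print a per-trace summary line.
#' @return list with \code{profiles} (list of
#'   \linkS4class{CompartmentProfile}, one per successful trace) and
#'   \code{diagnostics} (data.frame: cell_id, homolog, objective,
#'   sdp_bound, ratio, n_rounds, sdp_iterations, converged, error).
#' @examples
#' sim <- simulatePopulation(syntheticConfig(nLoci = 15, nCells = 2))
#' res <- callCompartments(sim$population, rBead = 200, seed = 1)
#' truthAccuracy(res$profiles, sim$truth)
#' @export
callCompartments <- function(population, rBead = 100, pruneFactor = 16,
                             gapMode = c("index", "bp"), epsilonZ = 0,
                             tolerance = 1e-6, thresholdRatio = 0.878,
                             maxRounds = 1000L, seed = 1L,
                             preprocess = TRUE, verbose = FALSE) {
    gapMode <- match.arg(gapMode)
    if (preprocess) population <- preprocessPopulation(population)
    trs <- traces(population)
    profiles <- list()
    diag <- vector("list", length(trs))
    for (i in seq_along(trs)) {
        tr <- trs[[i]]
        row <- data.frame(cell_id = tr@cellId, homolog = tr@homolog,
            objective = NA_real_, sdp_bound = NA_real_, ratio = NA_real_,
            n_rounds = NA_integer_, sdp_iterations = NA_integer_,
            converged = NA, error = NA_character_)
        res <- tryCatch({
            g <- buildGraph(tr, rBead = rBead, pruneFactor = pruneFactor,
                gapMode = gapMode, resolution = population@resolution,
                epsilonZ = epsilonZ)
            sdp <- solveSdp(laplacian(g), tolerance = tolerance)
            V <- approxFactorize(sdp@A)$V
            cut <- roundHyperplane(V, laplacian(g),
                sdpBound = sdp@sdpBound, thresholdRatio = thresholdRatio,
                maxRounds = maxRounds, seed = seed + i)
            spd <- if (length(tr@speckleDist)) tr@speckleDist else
                intensityToPseudoDist(tr@speckleIntensity)
            prof <- assignAB(cut, spd, cellId = tr@cellId,
                homolog = tr@homolog)
            list(prof = prof, sdp = sdp, cut = cut)
        }, error = function(e) e)
        if (inherits(res, "error")) {
            warning("trace ", tr@cellId, " (homolog ", tr@homolog,
                ") skipped: ", conditionMessage(res), call. = FALSE)
            row$error <- conditionMessage(res)
        } else {
            profiles[[length(profiles) + 1L]] <- res$prof
            row$objective <- res$cut@objective
            row$sdp_bound <- res$cut@sdpBound
            row$ratio <- res$cut@objective / max(res$cut@sdpBound,
                .Machine$double.eps)
            row$n_rounds <- res$cut@nRounds
            row$sdp_iterations <- res$sdp@iterations
            row$converged <- res$sdp@converged
            if (verbose)
                message(sprintf(
                    "%s/%s: cut %.4f / bound %.4f (ratio %.3f), %d draws",
                    tr@cellId, tr@homolog, row$objective, row$sdp_bound,
                    row$ratio, row$n_rounds))
        }
        diag[[i]] <- row
    }
    if (!length(profiles))
        stop("all traces failed; see warnings")
    list(profiles = profiles, diagnostics = do.call(rbind, diag))
}

#' Compare two compartment profiles
#'
#' Pearson correlation over usable bins via [profileCorrelation()],
#' accepting \linkS4class{EnsembleCompartments} (its normalized
#' frequency is used) or plain numeric vectors.
#'
#' @param x,y profiles to compare.
#' @return Pearson r.
#' @export
compareProfiles <- function(x, y) {
    toVec <- function(v) {
        if (is(v, "EnsembleCompartments")) v@fNorm else as.numeric(v)
    }
    profileCorrelation(toVec(x), toVec(y))
}
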
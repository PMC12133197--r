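#' @rdname accessors
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setGeneric("homolog", function(x) standardGeneric("homolog"))

#' @rdname accessors
#' @export
setGeneric("tracePanel", function(x) standardGeneric("tracePanel"))

#' @rdname accessors
#' @export
setGeneric("traceCoords", function(x) standardGeneric("traceCoords"))

#' @rdname accessors
#' @export
setGeneric("speckleDist", function(x) standardGeneric("speckleDist"))

#' @rdname accessors
#' @export
setGeneric("laminaDist", function(x) standardGeneric("laminaDist"))

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("laplacian", function(x) standardGeneric("laplacian"))

#' @rdname accessors
#' @export
setGeneric("speckleZ", function(x) standardGeneric("speckleZ"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("cEns", function(x) standardGeneric("cEns"))

#' @rdname accessors
#' @export
setGeneric("cutLabels", function(x) standardGeneric("cutLabels"))

#' @rdname accessors
#' @export
setGeneric("cutValue", function(x) standardGeneric("cutValue"))

#' @rdname accessors
#' @export
setGeneric("sdpBound", function(x) standardGeneric("sdpBound"))
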
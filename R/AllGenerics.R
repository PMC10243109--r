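#' @rdname SpectrumSet-class
#' @param object,x a \linkS4class{SpectrumSet} or
#'   \linkS4class{QuantizedSpectrumSet}.
#' @export
setGeneric("identifiers", function(x) standardGeneric("identifiers"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))

#' @rdname SpectrumSet-class
#' @export
setGeneric("peaksData", function(x) standardGeneric("peaksData"))

#' @rdname PackedHVSet-class
#' @param x object to query.
#' @export
setGeneric("hvDim", function(x) standardGeneric("hvDim"))

#' @rdname PackedHVSet-class
#' @export
setGeneric("hvWords", function(x) standardGeneric("hvWords"))
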
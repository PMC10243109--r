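# Accessors, show and subsetting for the S4 containers.

#' @rdname SpectrumSet-class
#' @export
setMethod("identifiers", "SpectrumSet", function(x) x@identifier)
#' @rdname SpectrumSet-class
#' @export
setMethod("precursorMz", "SpectrumSet", function(x) x@precursorMz)
#' @rdname SpectrumSet-class
#' @export
setMethod("precursorCharge", "SpectrumSet", function(x) x@precursorCharge)
#' @rdname SpectrumSet-class
#' @export
setMethod("peaksData", "SpectrumSet", function(x) x@peaks)
#' @rdname SpectrumSet-class
#' @export
setMethod("length", "SpectrumSet", function(x) length(x@identifier))

#' @rdname SpectrumSet-class
#' @param i index vector for subsetting.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SpectrumSet", function(x, i, j, ..., drop = FALSE) {
    new("SpectrumSet",
        identifier = x@identifier[i],
        precursorMz = x@precursorMz[i],
        precursorCharge = x@precursorCharge[i],
        peaks = x@peaks[i],
        metadata = x@metadata)
})

setMethod("show", "SpectrumSet", function(object) {
    cat("SpectrumSet with", length(object), "spectra\n")
    if (length(object) > 0L) {
        cat("  precursor m/z:", sprintf("%.4f-%.4f Da", min(object@precursorMz),
                                        max(object@precursorMz)), "\n")
        cat("  charges:", paste(sort(unique(object@precursorCharge)),
                                collapse = ", "), "\n")
    }
    if (length(object@metadata))
        cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
    invisible(NULL)
})

#' @rdname QuantizedSpectrumSet-class
#' @param x a \linkS4class{QuantizedSpectrumSet}.
#' @export
setMethod("identifiers", "QuantizedSpectrumSet", function(x) x@identifier)
#' @rdname QuantizedSpectrumSet-class
#' @export
setMethod("precursorMz", "QuantizedSpectrumSet", function(x) x@precursorMz)
#' @rdname QuantizedSpectrumSet-class
#' @export
setMethod("precursorCharge", "QuantizedSpectrumSet", function(x) x@precursorCharge)
#' @rdname QuantizedSpectrumSet-class
#' @export
setMethod("length", "QuantizedSpectrumSet", function(x) length(x@identifier))

#' @rdname QuantizedSpectrumSet-class
#' @param object a \linkS4class{QuantizedSpectrumSet}.
#' @export
setMethod("show", "QuantizedSpectrumSet", function(object) {
    cat("QuantizedSpectrumSet with", length(object), "spectra\n")
    cat("  f =", object@f, "m/z bins, Q =", object@Q, "intensity levels\n")
    invisible(NULL)
})

#' Bin and level vectors of a quantized spectrum
#'
#' @param x a \linkS4class{QuantizedSpectrumSet}.
#' @return list of integer vectors, one per spectrum.
#' @export
quantizedBins <- function(x) {
    stopifnot(is(x, "QuantizedSpectrumSet"))
    x@bins
}

#' @rdname quantizedBins
#' @export
quantizedLevels <- function(x) {
    stopifnot(is(x, "QuantizedSpectrumSet"))
    x@levels
}

#' @rdname HvCodebook-class
#' @param object a \linkS4class{HvCodebook}.
#' @export
setMethod("show", "HvCodebook", function(object) {
    cat("HvCodebook: D =", object@D, "bits,",
        object@f, "ID HVs,", object@Q, "level HVs\n")
    cat("  flipId =", object@flipId, ", flipLevel =", object@flipLevel,
        ", seed =", object@seed, "\n")
    invisible(NULL)
})

#' @rdname PackedHVSet-class
#' @export
setMethod("hvDim", "PackedHVSet", function(x) x@D)
#' @rdname PackedHVSet-class
#' @export
setMethod("hvWords", "PackedHVSet", function(x) x@words)
#' @rdname PackedHVSet-class
#' @export
setMethod("length", "PackedHVSet", function(x) nrow(x@words))

#' @rdname PackedHVSet-class
#' @param i row index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PackedHVSet", function(x, i, j, ..., drop = FALSE) {
    new("PackedHVSet", words = x@words[i, , drop = FALSE], D = x@D)
})

#' @rdname PackedHVSet-class
#' @param object a \linkS4class{PackedHVSet}.
#' @export
setMethod("show", "PackedHVSet", function(object) {
    cat("PackedHVSet:", length(object), "hypervectors of", object@D,
        "bits (", ncol(object@words), "words each )\n")
    invisible(NULL)
})
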
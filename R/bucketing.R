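# Precursor-mass bucket division.

# hydrogen mass carried by each charge, and the spacing between centers of
# adjacent clusters of physically possible peptide masses
.HYDROGEN_MASS <- 1.00794
.PEPTIDE_MASS_SPACING <- 1.0005079

#' Integer precursor-mass bucket of a spectrum
#'
#' Maps a precursor to \code{floor(charge * (precursorMz - 1.00794) /
#' 1.0005079)}: the charge-scaled neutral mass divided by the 1.0005079 Da
#' spacing between centers of adjacent clusters of physically possible
#' peptide masses. Spectra are later compared only within a bucket, turning
#' the quadratic all-pairs distance computation into a sum of small
#' per-bucket problems. Flooring makes buckets left-closed intervals of
#' width 1.0005079 Da in neutral-mass space; set \code{rounding = "round"}
#' for sensitivity checks.
#'
#' @param precursorMz numeric vector of precursor m/z (Da), each
#'   >= 1.00794.
#' @param charge integer vector of precursor charges (recycled).
#' @param rounding \code{"floor"} (default) or \code{"round"}.
#' @return non-negative integer vector of bucket indices, non-decreasing in
#'   \code{precursorMz} at fixed charge.
#' @examples
#' bucketIndex(500.5, 2L)  # 998
#' @export
bucketIndex <- function(precursorMz, charge, rounding = c("floor", "round")) {
    rounding <- match.arg(rounding)
    if (any(precursorMz < .HYDROGEN_MASS))
        stop("precursor m/z below the hydrogen mass (degenerate precursor)")
    x <- charge * (precursorMz - .HYDROGEN_MASS) / .PEPTIDE_MASS_SPACING
    as.integer(if (rounding == "floor") floor(x) else round(x))
}

#' Divide spectra into precursor-mass buckets
#'
#' Assigns every quantized spectrum to exactly one bucket keyed by
#' (charge, bucket index) — or by bucket index alone when
#' \code{splitByCharge = FALSE} — with members sorted by ascending
#' precursor m/z within each bucket.
#'
#' @param x a \linkS4class{QuantizedSpectrumSet}.
#' @param splitByCharge keep charge states in separate buckets (default
#'   TRUE; the index formula alone would co-bucket different charges only
#'   coincidentally).
#' @param rounding passed to [bucketIndex()].
#' @return named list of integer ordinal vectors (1-based positions into
#'   \code{x}); names are \code{"<charge>:<index>"} keys, ordered by charge
#'   then index. Attribute \code{"n"} records \code{length(x)}.
#' @export
assignBuckets <- function(x, splitByCharge = TRUE, rounding = "floor") {
    stopifnot(is(x, "QuantizedSpectrumSet"))
    n <- length(x)
    if (n == 0L) {
        out <- list()
        attr(out, "n") <- 0L
        return(out)
    }
    idx <- bucketIndex(x@precursorMz, x@precursorCharge, rounding)
    z <- if (splitByCharge) x@precursorCharge else rep(0L, n)
    key <- paste0(z, ":", idx)
    ord <- order(x@precursorMz)
    table <- split(ord, key[ord])
    # deterministic bucket order: by charge, then index
    parts <- do.call(rbind, strsplit(names(table), ":", fixed = TRUE))
    o <- order(as.integer(parts[, 1L]), as.integer(parts[, 2L]))
    table <- table[o]
    attr(table, "n") <- n
    table
}
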
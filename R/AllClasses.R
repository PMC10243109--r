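#' @import methods
NULL

#' Container for parsed MS/MS spectra
#'
#' Holds one record per spectrum read from a Mascot Generic Format (MGF)
#' file: a stable identifier, precursor m/z (Da), precursor charge, and the
#' peak list as a two-column \code{matrix} (columns \code{mz},
#' \code{intensity}) sorted by ascending m/z. Parsing statistics (blocks
#' read, skipped, charge-filtered) travel in \code{metadata}.
#'
#' @slot identifier character vector of spectrum identifiers.
#' @slot precursorMz numeric vector of precursor m/z values in Da.
#' @slot precursorCharge integer vector of precursor charge states.
#' @slot peaks list of numeric matrices, one per spectrum, columns
#'   \code{mz} and \code{intensity}.
#' @slot metadata named list of provenance and counts.
#'
#' @seealso [readMgf()], [preprocessSpectra()]
#' @export
setClass("SpectrumSet",
    representation(
        identifier = "character",
        precursorMz = "numeric",
        precursorCharge = "integer",
        peaks = "list",
        metadata = "list"
    ),
    prototype(metadata = list())
)

setValidity("SpectrumSet", function(object) {
    n <- length(object@identifier)
    msg <- character()
    if (length(object@precursorMz) != n || length(object@precursorCharge) != n ||
        length(object@peaks) != n)
        msg <- c(msg, "identifier, precursorMz, precursorCharge and peaks must have equal length")
    if (n > 0L) {
        if (any(!is.finite(object@precursorMz)) || any(object@precursorMz <= 0))
            msg <- c(msg, "precursorMz must be positive and finite")
        if (any(is.na(object@precursorCharge)) || any(object@precursorCharge < 1L))
            msg <- c(msg, "precursorCharge must be a positive integer")
        ok <- vapply(object@peaks, function(p) {
            is.matrix(p) && ncol(p) == 2L &&
                (nrow(p) == 0L || (all(p[, 1L] > 0) && all(p[, 2L] >= 0) &&
                                   !is.unsorted(p[, 1L])))
        }, logical(1))
        if (!all(ok))
            msg <- c(msg, "each peak matrix needs 2 columns, positive m/z sorted ascending, non-negative intensities")
    }
    if (length(msg)) msg else TRUE
})

#' Quantized sparse spectra ready for hyperdimensional encoding
#'
#' Each spectrum is reduced to parallel integer vectors: m/z bin indices
#' (0-based, strictly increasing, in \code{[0, f)}) and intensity levels
#' (1-based, in \code{[1, Q]}). \code{f} is the derived maximum bin count
#' \code{ceiling((maxMz - minMz)/binSize)} and \code{Q} the number of
#' intensity quantization levels.
#'
#' @slot identifier,precursorMz,precursorCharge per-spectrum annotation,
#'   as in \linkS4class{SpectrumSet}.
#' @slot bins list of integer vectors of m/z bin indices.
#' @slot levels list of integer vectors of intensity levels.
#' @slot f integer, number of m/z bins (ID codebook size).
#' @slot Q integer, number of intensity levels (level codebook size).
#' @slot params the [preprocessParams()] list used to produce the object.
#'
#' @export
setClass("QuantizedSpectrumSet",
    representation(
        identifier = "character",
        precursorMz = "numeric",
        precursorCharge = "integer",
        bins = "list",
        levels = "list",
        f = "integer",
        Q = "integer",
        params = "list"
    )
)

setValidity("QuantizedSpectrumSet", function(object) {
    n <- length(object@identifier)
    msg <- character()
    if (length(object@bins) != n || length(object@levels) != n ||
        length(object@precursorMz) != n || length(object@precursorCharge) != n)
        msg <- c(msg, "parallel slots must have equal length")
    if (n > 0L) {
        okb <- vapply(seq_len(n), function(i) {
            b <- object@bins[[i]]; l <- object@levels[[i]]
            length(b) == length(l) && length(b) >= 1L &&
                all(b >= 0L) && all(b < object@f) &&
                all(l >= 1L) && all(l <= object@Q) &&
                !is.unsorted(b, strictly = TRUE)
        }, logical(1))
        if (!all(okb))
            msg <- c(msg, "bins must be strictly increasing in [0, f) with levels in [1, Q]")
    }
    if (length(msg)) msg else TRUE
})

#' ID and level hypervector codebooks
#'
#' The two stochastic codebooks used by the encoder: \code{f} ID
#' hypervectors indexed by m/z bin and \code{Q} level hypervectors indexed
#' by intensity level, each a D-bit binary vector stored bit-packed as
#' \code{ceiling(D/32)} 32-bit words per row. Consecutive rows differ in
#' exactly \code{flipId} (resp. \code{flipLevel}) uniformly chosen bits, so
#' nearby m/z bins and nearby intensity levels map to nearby hypervectors.
#' A tie-break hypervector resolves even-split votes during majority
#' bundling so that encoding is deterministic.
#'
#' @slot D integer, hypervector dimension in bits.
#' @slot f,Q integer codebook sizes.
#' @slot seed integer seed that generated the codebook.
#' @slot flipId,flipLevel bits flipped between consecutive rows.
#' @slot idWords,levelWords integer matrices (rows = hypervectors,
#'   columns = packed 32-bit words).
#' @slot tieWords packed tie-break hypervector.
#'
#' @seealso [generateCodebook()], [encodeSpectra()]
#' @export
setClass("HvCodebook",
    representation(
        D = "integer", f = "integer", Q = "integer",
        seed = "integer", flipId = "integer", flipLevel = "integer",
        idWords = "matrix", levelWords = "matrix", tieWords = "integer"
    )
)

setValidity("HvCodebook", function(object) {
    W <- as.integer((object@D + 31L) %/% 32L)
    msg <- character()
    if (object@D < 32L) msg <- c(msg, "D must be at least 32")
    if (ncol(object@idWords) != W || ncol(object@levelWords) != W ||
        length(object@tieWords) != W)
        msg <- c(msg, "packed word width must equal ceiling(D/32)")
    if (nrow(object@idWords) != object@f) msg <- c(msg, "idWords must have f rows")
    if (nrow(object@levelWords) != object@Q) msg <- c(msg, "levelWords must have Q rows")
    if (object@flipId < 1L || object@flipId > object@D ||
        object@flipLevel < 1L || object@flipLevel > object@D)
        msg <- c(msg, "flip counts must be in [1, D]")
    if (length(msg)) msg else TRUE
})

#' Set of bit-packed binary hypervectors
#'
#' One D-bit hypervector per row, packed into \code{ceiling(D/32)} 32-bit
#' words; bits at positions >= D are zero. This storage is exactly 1/8 the
#' bytes of byte-per-bit storage.
#'
#' @slot words integer matrix, rows = hypervectors, columns = packed words.
#' @slot D integer bit length.
#'
#' @seealso [encodeSpectra()], [hammingDistance()]
#' @export
setClass("PackedHVSet",
    representation(words = "matrix", D = "integer")
)

setValidity("PackedHVSet", function(object) {
    W <- as.integer((object@D + 31L) %/% 32L)
    msg <- character()
    if (!is.integer(object@words)) msg <- c(msg, "words must be an integer matrix")
    if (ncol(object@words) != W)
        msg <- c(msg, "word count per row must equal ceiling(D/32)")
    if (object@D >= 1L && ncol(object@words) > 0L && nrow(object@words) > 0L) {
        pad <- object@D %% 32L
        if (pad != 0L) {
            mask <- as.integer(2^pad - 1)  # pad <= 31 so this fits an int
            last <- object@words[, W]
            if (any(bitwAnd(last, bitwNot(mask)) != 0L))
                msg <- c(msg, "bits at positions >= D must be zero")
        }
    }
    if (length(msg)) msg else TRUE
})
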
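# Codebook generation, bit packing and majority-bundle encoding.

#' Pack a 0/1 vector into 32-bit words and back
#'
#' Bit position p (0-based) maps to word \code{p \%/\% 32}, bit
#' \code{p \%\% 32} (little-endian within word); bits at positions >= D are
#' zero, so a D-bit hypervector occupies exactly \code{ceiling(D/32)} words
#' — 1/8 the bytes of byte-per-bit storage.
#'
#' @param bits integer/numeric vector of 0s and 1s.
#' @return \code{packHvBits}: a \linkS4class{PackedHVSet} of one row;
#'   \code{unpackHvBits}: an integer 0/1 matrix with one row per
#'   hypervector and D columns.
#' @examples
#' x <- rep(c(1L, 0L), 50)
#' all(unpackHvBits(packHvBits(x))[1, ] == x)
#' @export
packHvBits <- function(bits) {
    bits <- as.integer(bits)
    new("PackedHVSet",
        words = matrix(cpp_pack_bits(bits), nrow = 1L),
        D = length(bits))
}

#' @rdname packHvBits
#' @param x a \linkS4class{PackedHVSet}.
#' @export
unpackHvBits <- function(x) {
    stopifnot(is(x, "PackedHVSet"))
    t(vapply(seq_len(length(x)),
             function(i) cpp_unpack_bits(x@words[i, ], x@D),
             integer(x@D)))
}

#' Default flip counts for codebook generation
#'
#' \code{max(1, round(D / (2 * n)))} bits flipped between consecutive
#' hypervectors, so that the first and last entries of an n-row codebook
#' approach orthogonality (Hamming distance near D/2) — the standard
#' locality-preserving design.
#'
#' @param D hypervector dimension in bits.
#' @param n codebook size (f for ID hypervectors, Q for level
#'   hypervectors).
#' @return integer flip count in \code{[1, D]}.
#' @export
defaultFlip <- function(D, n) {
    max(1L, as.integer(round(D / (2 * n))))
}

#' Generate the ID and level hypervector codebooks
#'
#' Both codebooks are generated iteratively and stochastically: the first
#' row is a uniform random D-bit vector and every following row flips
#' exactly \code{flipId} (ID codebook) or \code{flipLevel} (level codebook)
#' distinct, uniformly chosen bits of its predecessor. Nearby m/z bins and
#' intensity levels therefore receive similar hypervectors, while distant
#' ones approach the D/2 distance of unrelated random vectors. A tie-break
#' hypervector for majority bundling is drawn from the same seeded stream.
#' The same seed and parameters always reproduce a bit-identical codebook.
#'
#' @param D hypervector dimension in bits (>= 32; default 2048).
#' @param f number of ID hypervectors (m/z bins).
#' @param Q number of level hypervectors (intensity levels; default 16).
#' @param seed integer RNG seed.
#' @param flipId,flipLevel bits flipped between consecutive rows; default
#'   [defaultFlip()].
#' @return a \linkS4class{HvCodebook}.
#' @export
generateCodebook <- function(D = 2048L, f, Q = 16L, seed = 1L,
                             flipId = defaultFlip(D, f),
                             flipLevel = defaultFlip(D, Q)) {
    D <- as.integer(D); f <- as.integer(f); Q <- as.integer(Q)
    flipId <- as.integer(flipId); flipLevel <- as.integer(flipLevel)
    stopifnot(D >= 32L, f >= 2L, Q >= 2L)
    if (flipId < 1L || flipId > D || flipLevel < 1L || flipLevel > D)
        stop("flip counts must be in [1, D]")
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(seed)
    id <- cpp_generate_hv_chain(f, D, flipId)
    lev <- cpp_generate_hv_chain(Q, D, flipLevel)
    tie <- cpp_random_hv(D)
    new("HvCodebook", D = D, f = f, Q = Q, seed = as.integer(seed),
        flipId = flipId, flipLevel = flipLevel,
        idWords = id, levelWords = lev, tieWords = tie)
}

.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Rows of a codebook as PackedHVSets
#'
#' @param cb a \linkS4class{HvCodebook}.
#' @return a \linkS4class{PackedHVSet} holding the ID rows, level rows, or
#'   the tie-break hypervector.
#' @export
idHvs <- function(cb) new("PackedHVSet", words = cb@idWords, D = cb@D)

#' @rdname idHvs
#' @export
levelHvs <- function(cb) new("PackedHVSet", words = cb@levelWords, D = cb@D)

#' @rdname idHvs
#' @export
tieHv <- function(cb) new("PackedHVSet", words = matrix(cb@tieWords, nrow = 1L),
                          D = cb@D)

#' Encode quantized spectra into binary hypervectors
#'
#' Each spectrum's peaks index the codebooks: peak (bin i, level j) binds
#' \code{I[i] XOR L[j]}, and the pointwise majority over all bound vectors
#' is the spectrum hypervector. An exact tie at a bit position (even peak
#' count, split vote) takes that position's bit of the codebook's tie-break
#' hypervector, keeping encoding deterministic. \code{encodeSpectra}
#' processes the set in batches of \code{batchSize}; results are
#' bit-identical for any batch size.
#'
#' @param x a \linkS4class{QuantizedSpectrumSet} (or, for
#'   \code{encodeSpectrum}, integer vectors \code{bins} and \code{levels}).
#' @param cb a \linkS4class{HvCodebook} with \code{f} and \code{Q} matching
#'   \code{x}.
#' @param batchSize spectra encoded per batch.
#' @return a \linkS4class{PackedHVSet} with one row per spectrum.
#' @export
encodeSpectra <- function(x, cb, batchSize = 1024L) {
    stopifnot(is(x, "QuantizedSpectrumSet"), is(cb, "HvCodebook"))
    if (x@f != cb@f || x@Q != cb@Q)
        stop("codebook f/Q do not match the quantized spectra")
    n <- length(x)
    W <- ncol(cb@idWords)
    if (n == 0L)
        return(new("PackedHVSet",
                   words = matrix(integer(0), nrow = 0L, ncol = W), D = cb@D))
    batchSize <- max(1L, as.integer(batchSize))
    starts <- seq.int(1L, n, by = batchSize)
    words <- matrix(0L, nrow = n, ncol = W)
    for (s in starts) {
        e <- min(n, s + batchSize - 1L)
        words[s:e, ] <- cpp_encode_batch(x@bins[s:e], x@levels[s:e],
                                         cb@idWords, cb@levelWords,
                                         cb@tieWords, cb@D)
    }
    new("PackedHVSet", words = words, D = cb@D)
}

#' @rdname encodeSpectra
#' @param bins integer vector of 0-based bin indices.
#' @param levels integer vector of 1-based intensity levels.
#' @export
encodeSpectrum <- function(bins, levels, cb) {
    stopifnot(is(cb, "HvCodebook"), length(bins) == length(levels),
              length(bins) >= 1L)
    w <- cpp_encode_batch(list(as.integer(bins)), list(as.integer(levels)),
                          cb@idWords, cb@levelWords, cb@tieWords, cb@D)
    new("PackedHVSet", words = w, D = cb@D)
}

#' Save or load a codebook
#'
#' Plain-text header (D, f, Q, seed, flip counts) followed by one row of
#' packed words per hypervector: ID rows, then level rows, then the
#' tie-break row. Loading reproduces a bit-identical codebook.
#'
#' @param cb a \linkS4class{HvCodebook}.
#' @param path file path.
#' @return \code{loadCodebook} returns the \linkS4class{HvCodebook}.
#' @export
saveCodebook <- function(cb, path) {
    stopifnot(is(cb, "HvCodebook"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("D=%d f=%d Q=%d seed=%d flipId=%d flipLevel=%d",
                       cb@D, cb@f, cb@Q, cb@seed, cb@flipId, cb@flipLevel), con)
    utils::write.table(rbind(cb@idWords, cb@levelWords, matrix(cb@tieWords, 1L)),
                       con, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname saveCodebook
#' @export
loadCodebook <- function(path) {
    hdr <- strsplit(readLines(path, n = 1L), " ")[[1L]]
    vals <- stats::setNames(as.integer(sub("^[^=]*=", "", hdr)),
                            sub("=.*$", "", hdr))
    m <- as.matrix(utils::read.table(path, skip = 1L, colClasses = "integer"))
    dimnames(m) <- NULL
    new("HvCodebook", D = vals[["D"]], f = vals[["f"]], Q = vals[["Q"]],
        seed = vals[["seed"]], flipId = vals[["flipId"]],
        flipLevel = vals[["flipLevel"]],
        idWords = m[seq_len(vals[["f"]]), , drop = FALSE],
        levelWords = m[vals[["f"]] + seq_len(vals[["Q"]]), , drop = FALSE],
        tieWords = m[nrow(m), ])
}
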
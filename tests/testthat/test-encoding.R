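test_that("pack/unpack is an exact round trip with ceil(D/32) words", {
    expect_equal(ncol(hvWords(packHvBits(rep(1L, 32)))), 1L)
    expect_equal(ncol(hvWords(packHvBits(rep(0L, 2048)))), 64L)
    set.seed(41)
    for (D in c(32L, 100L, 2048L)) {
        bits <- sample(c(0L, 1L), D, replace = TRUE)
        phv <- packHvBits(bits)
        expect_equal(ncol(hvWords(phv)), as.integer(ceiling(D / 32)))
        expect_equal(as.integer(unpackHvBits(phv)[1, ]), bits)
        expect_true(validObject(phv))  # padding bits beyond D are zero
    }
    expect_error(packHvBits(c(0L, 2L, 1L)), "0 and 1")
})

test_that("packed storage uses exactly 1/8 the bytes of byte-per-bit storage", {
    for (D in c(128L, 1024L, 2048L)) {
        phv <- packHvBits(sample(c(0L, 1L), D, replace = TRUE))
        packed_bytes <- ncol(hvWords(phv)) * 4L
        expect_equal(packed_bytes, D / 8L)
    }
})

test_that("consecutive codebook rows differ in exactly the configured flip counts", {
    cb <- generateCodebook(D = 256L, f = 40L, Q = 8L, seed = 5L,
                           flipId = 3L, flipLevel = 16L)
    ids <- unpackHvBits(idHvs(cb))
    for (k in seq_len(39L))
        expect_equal(sum(ids[k, ] != ids[k + 1L, ]), 3L)
    levs <- unpackHvBits(levelHvs(cb))
    for (k in seq_len(7L))
        expect_equal(sum(levs[k, ] != levs[k + 1L, ]), 16L)
    expect_error(generateCodebook(D = 64L, f = 4L, Q = 4L, seed = 1L,
                                  flipId = 0L), "flip")
    expect_error(generateCodebook(D = 64L, f = 4L, Q = 4L, seed = 1L,
                                  flipLevel = 65L), "flip")
})

test_that("same seed and parameters reproduce a bit-identical codebook", {
    a <- generateCodebook(D = 128L, f = 20L, Q = 16L, seed = 17L)
    b <- generateCodebook(D = 128L, f = 20L, Q = 16L, seed = 17L)
    expect_identical(a@idWords, b@idWords)
    expect_identical(a@levelWords, b@levelWords)
    expect_identical(a@tieWords, b@tieWords)
    c <- generateCodebook(D = 128L, f = 20L, Q = 16L, seed = 18L)
    expect_false(identical(a@idWords, c@idWords))
})

test_that("chained flips respect the triangle inequality on a small instance", {
    cb <- generateCodebook(D = 32L, f = 4L, Q = 2L, seed = 3L, flipId = 8L,
                           flipLevel = 1L)
    ids <- unpackHvBits(idHvs(cb))
    expect_lte(sum(ids[1, ] != ids[3, ]), 16L)  # two 8-bit steps at most add
})

test_that("default flip counts drive distant codebook entries toward D/2", {
    expect_equal(defaultFlip(2048L, 16L), 64L)
    expect_equal(defaultFlip(2048L, 27980L), 1L)
    # locality: mean distance between rows grows with index separation until
    # it saturates near D/2
    cb <- generateCodebook(D = 1024L, f = 256L, Q = 16L, seed = 7L,
                           flipId = defaultFlip(1024L, 256L))
    ids <- idHvs(cb)
    mean_d <- function(sep) {
        starts <- seq(1L, 256L - sep, by = 8L)
        mean(vapply(starts, function(s) hammingDistance(ids, i = s, j = s + sep),
                    numeric(1)))
    }
    d_small <- mean_d(4L); d_mid <- mean_d(64L); d_far <- mean_d(224L)
    expect_lt(d_small, d_mid)
    expect_lte(d_mid, d_far + 0.05)   # saturation tolerance near D/2
    expect_gt(d_far, 0.3)
})

toy_codebook <- function() {
    # hand-built D = 32 codebook with 3 IDs and 2 levels
    id_bits <- rbind(c(rep(1L, 16), rep(0L, 16)),
                     rep(c(1L, 0L), 16),
                     rep(0L, 32))
    lev_bits <- rbind(rep(c(0L, 0L, 1L, 1L), 8),
                      rep(1L, 32))
    tie_bits <- rep(c(1L, 0L), 16)
    new("HvCodebook", D = 32L, f = 3L, Q = 2L, seed = 0L,
        flipId = 1L, flipLevel = 1L,
        idWords = rbind(hvWords(packHvBits(id_bits[1, ])),
                        hvWords(packHvBits(id_bits[2, ])),
                        hvWords(packHvBits(id_bits[3, ]))),
        levelWords = rbind(hvWords(packHvBits(lev_bits[1, ])),
                           hvWords(packHvBits(lev_bits[2, ]))),
        tieWords = as.integer(hvWords(packHvBits(tie_bits))))
}

test_that("a single-peak spectrum encodes to I XOR L exactly", {
    cb <- toy_codebook()
    h <- encodeSpectrum(bins = 1L, levels = 2L, cb)
    expected <- bitwXor(unpackHvBits(idHvs(cb))[2, ],
                        unpackHvBits(levelHvs(cb))[2, ])
    expect_equal(as.integer(unpackHvBits(h)[1, ]), expected)
})

test_that("majority bundling matches a hand-computed bitwise majority with tie-break", {
    cb <- toy_codebook()
    bins <- c(0L, 1L, 2L); levels <- c(1L, 2L, 1L)
    ids <- unpackHvBits(idHvs(cb)); levs <- unpackHvBits(levelHvs(cb))
    bound <- rbind(bitwXor(ids[1, ], levs[1, ]),
                   bitwXor(ids[2, ], levs[2, ]),
                   bitwXor(ids[3, ], levs[1, ]))
    expected <- as.integer(colSums(bound) > 1.5)  # odd count: clean majority
    h <- encodeSpectrum(bins, levels, cb)
    expect_equal(as.integer(unpackHvBits(h)[1, ]), expected)
    # even peak count: split votes take the tie-break hypervector bit
    bins2 <- c(0L, 2L); levels2 <- c(1L, 1L)
    bound2 <- rbind(bitwXor(ids[1, ], levs[1, ]), bitwXor(ids[3, ], levs[1, ]))
    cs <- colSums(bound2)
    tie_bits <- as.integer(unpackHvBits(tieHv(cb))[1, ])
    expected2 <- ifelse(cs > 1, 1L, ifelse(cs < 1, 0L, tie_bits))
    h2 <- encodeSpectrum(bins2, levels2, cb)
    expect_equal(as.integer(unpackHvBits(h2)[1, ]), expected2)
})

test_that("encoding is deterministic and invariant to peak order", {
    cb <- generateCodebook(D = 128L, f = 50L, Q = 16L, seed = 9L)
    bins <- c(3L, 10L, 22L, 31L, 47L); levels <- c(1L, 16L, 8L, 4L, 12L)
    h1 <- encodeSpectrum(bins, levels, cb)
    h2 <- encodeSpectrum(bins, levels, cb)
    expect_identical(hvWords(h1), hvWords(h2))
    o <- c(4L, 1L, 5L, 3L, 2L)
    h3 <- encodeSpectrum(bins[o], levels[o], cb)
    expect_identical(hvWords(h1), hvWords(h3))
    expect_error(encodeSpectrum(60L, 1L, cb), "range")
    expect_error(encodeSpectrum(3L, 17L, cb), "range")
})

random_quantized <- function(n, f = 200L, Q = 16L) {
    bins <- lapply(seq_len(n), function(i)
        sort(sample(0:(f - 1L), sample(5:40, 1))))
    levels <- lapply(bins, function(b)
        sample(seq_len(Q), length(b), replace = TRUE))
    new("QuantizedSpectrumSet",
        identifier = sprintf("s%d", seq_len(n)),
        precursorMz = runif(n, 300, 1200),
        precursorCharge = rep(2L, n),
        bins = bins, levels = levels,
        f = f, Q = Q, params = list())
}

test_that("batched encoding is bit-identical to the scalar path for any batch size", {
    set.seed(43)
    q <- random_quantized(100L)
    cb <- generateCodebook(D = 128L, f = 200L, Q = 16L, seed = 2L)
    scalar <- do.call(rbind, lapply(seq_len(100L), function(i)
        hvWords(encodeSpectrum(q@bins[[i]], q@levels[[i]], cb))))
    for (bs in c(1L, 7L, 100L, 1024L)) {
        batch <- encodeSpectra(q, cb, batchSize = bs)
        expect_identical(hvWords(batch), scalar)
    }
    empty <- encodeSpectra(random_quantized(0L), cb)
    expect_equal(length(empty), 0L)
})

test_that("codebooks survive a save/load round trip bit-identically", {
    cb <- generateCodebook(D = 96L, f = 10L, Q = 4L, seed = 77L)
    path <- tempfile(fileext = ".txt")
    saveCodebook(cb, path)
    cb2 <- loadCodebook(path)
    expect_identical(cb@idWords, cb2@idWords)
    expect_identical(cb@levelWords, cb2@levelWords)
    expect_identical(cb@tieWords, cb2@tieWords)
    expect_equal(cb@seed, cb2@seed)
    expect_equal(cb@flipId, cb2@flipId)
})
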
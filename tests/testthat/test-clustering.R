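test_that("normalized Hamming distance: identity 0, complement 1, packed equals per-bit", {
    set.seed(51)
    bits <- random_bits(1L, 2048L)
    h <- pack_rows(bits)
    expect_equal(hammingDistance(h, h), 0)
    expect_equal(hammingDistance(h, complementHv(h)), 1)
    # packed-word computation equals the naive per-bit loop on random pairs
    for (D in c(128L, 100L)) {
        a_bits <- random_bits(1L, D)[1, ]; b_bits <- random_bits(1L, D)[1, ]
        expect_equal(hammingDistance(packHvBits(a_bits), packHvBits(b_bits)),
                     naive_hamming(a_bits, b_bits))
    }
    expect_error(hammingDistance(packHvBits(rep(0L, 64)),
                                 packHvBits(rep(0L, 32))), "mismatch")
})

test_that("condensed bucket matrices match a brute-force double loop", {
    set.seed(52)
    for (n in c(2L, 10L, 30L)) {
        bits <- random_bits(n, 160L)
        hvs <- pack_rows(bits)
        dm <- bucketDistanceMatrix(hvs)
        expect_s3_class(dm, "dist")
        expect_equal(length(dm), n * (n - 1L) / 2L)
        expect_true(all(dm >= 0 & dm <= 1))
        m <- as.matrix(dm)
        for (i in seq_len(n - 1L))
            for (j in (i + 1L):n)
                expect_equal(m[i, j], naive_hamming(bits[i, ], bits[j, ]))
    }
    # degenerate buckets
    expect_equal(length(bucketDistanceMatrix(pack_rows(random_bits(1L, 64L)))), 0L)
    # two identical HVs -> condensed [0]; complement pair present -> a 1.0
    b <- random_bits(1L, 64L)
    two <- pack_rows(rbind(b, b))
    expect_equal(as.numeric(bucketDistanceMatrix(two)), 0)
    three <- pack_rows(rbind(b, 1L - b, random_bits(1L, 64L)))
    expect_true(any(as.numeric(bucketDistanceMatrix(three)) == 1))
})

hand_dm <- function() {
    # two tight pairs far apart: (1,2) and (3,4) at 0.05, cross pairs 0.6
    m <- matrix(0.6, 4, 4); diag(m) <- 0
    m[1, 2] <- m[2, 1] <- 0.05
    m[3, 4] <- m[4, 3] <- 0.05
    stats::as.dist(m)
}

test_that("both algorithms recover two tight pairs in the hand-built matrix", {
    for (alg in c("hierarchical", "dbscan")) {
        lab <- clusterBucket(hand_dm(), algorithm = alg, eps = 0.25)
        expect_equal(lab[1], lab[2])
        expect_equal(lab[3], lab[4])
        expect_false(lab[1] == lab[3])
        expect_true(all(lab >= 0L))
        expect_equal(sort(unique(lab)), c(0L, 1L))
    }
})

test_that("eps boundaries: close pair joins, all-far points become noise", {
    m <- matrix(0.1, 2, 2); diag(m) <- 0
    for (alg in c("hierarchical", "dbscan"))
        expect_equal(clusterBucket(stats::as.dist(m), alg, eps = 0.25), c(0L, 0L))
    far <- matrix(0.5, 3, 3); diag(far) <- 0
    for (alg in c("hierarchical", "dbscan"))
        expect_equal(clusterBucket(stats::as.dist(far), alg, eps = 0.25),
                     rep(-1L, 3))
    expect_error(clusterBucket(hand_dm(), "hierarchical", eps = 1.5), "eps")
    expect_equal(clusterBucket(bucketDistanceMatrix(pack_rows(random_bits(1L, 64L))),
                               "hierarchical"), -1L)
})

test_that("complete linkage bounds intra-cluster distances by eps", {
    set.seed(53)
    for (k in 1:10) {
        n <- sample(5:25, 1)
        m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
        dm <- stats::as.dist(m)
        lab <- clusterBucket(dm, "hierarchical", eps = 0.3)
        for (cl in unique(lab[lab >= 0L])) {
            members <- which(lab == cl)
            expect_lte(max(m[members, members]), 0.3)
        }
    }
})

test_that("DBSCAN clusters chain: every member has a co-member within eps", {
    set.seed(54)
    for (k in 1:10) {
        n <- sample(5:25, 1)
        m <- matrix(runif(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
        lab <- clusterBucket(stats::as.dist(m), "dbscan", eps = 0.3)
        for (cl in unique(lab[lab >= 0L])) {
            members <- which(lab == cl)
            expect_gte(length(members), 2L)
            for (i in members)
                expect_lte(min(m[i, setdiff(members, i)]), 0.3)
        }
        # noise points have no neighbor within eps among all points
        for (i in which(lab == -1L))
            expect_gt(min(m[i, -i]), 0.3)
    }
})

test_that("clustering is invariant to input order up to relabeling", {
    set.seed(55)
    bits <- rbind(random_bits(3L, 256L)[rep(1:3, each = 4), ] , random_bits(3L, 256L))
    noise <- random_bits(nrow(bits), 256L)
    flip <- noise * (matrix(runif(length(noise)), nrow(noise)) < 0.02)
    bits <- abs(bits - flip)  # small perturbations around 3 planted centers
    hvs <- pack_rows(bits)
    for (alg in c("hierarchical", "dbscan")) {
        lab <- clusterBucket(bucketDistanceMatrix(hvs), alg, eps = 0.25)
        perm <- sample(nrow(bits))
        lab_p <- clusterBucket(bucketDistanceMatrix(pack_rows(bits[perm, ])),
                               alg, eps = 0.25)
        lab_back <- integer(length(lab_p))
        lab_back[perm] <- lab_p  # undo the permutation
        expect_true(same_partition(lab, lab_back))
    }
})

test_that("global labels are unique across buckets and singles stay -1", {
    set.seed(56)
    centers <- random_bits(4L, 128L)
    bits <- centers[c(1, 1, 2, 2, 3, 4, 4, 4), ]
    hvs <- pack_rows(bits)
    q <- new("QuantizedSpectrumSet",
             identifier = paste0("s", 1:8),
             precursorMz = c(500.1, 500.2, 500.15, 500.18, 700.5, 900.2, 900.25, 900.3),
             precursorCharge = rep(2L, 8),
             bins = rep(list(c(0L, 1L, 2L, 3L, 4L)), 8),
             levels = rep(list(rep(1L, 5)), 8),
             f = 100L, Q = 16L, params = list())
    tb <- assignBuckets(q)
    a <- runAllBuckets(q, tb, hvs, algorithm = "hierarchical", eps = 0.25)
    expect_equal(nrow(a), 8L)
    expect_equal(a$identifier, identifiers(q))
    # bucket with the lone spectrum (700.5) -> label -1
    expect_equal(a$cluster_label[5], -1L)
    # labels >= 0 never span two buckets
    pos <- a$cluster_label >= 0L
    expect_equal(anyDuplicated(unique(a[pos, c("bucket", "cluster_label")])$cluster_label), 0L)
    spans <- tapply(a$bucket[pos], a$cluster_label[pos],
                    function(b) length(unique(b)))
    expect_true(all(spans == 1L))
    # label count equals the sum of per-bucket cluster counts
    per_bucket <- tapply(a$cluster_label[pos], a$bucket[pos],
                         function(l) length(unique(l)))
    expect_equal(length(unique(a$cluster_label[pos])), sum(per_bucket))
    # empty table -> empty assignment
    empty_q <- new("QuantizedSpectrumSet", identifier = character(0),
                   precursorMz = numeric(0), precursorCharge = integer(0),
                   bins = list(), levels = list(), f = 100L, Q = 16L,
                   params = list())
    empty_hvs <- new("PackedHVSet",
                     words = matrix(integer(0), 0L, 4L), D = 128L)
    ea <- runAllBuckets(empty_q, assignBuckets(empty_q), empty_hvs)
    expect_equal(nrow(ea), 0L)
})

test_that("run over two size-1 buckets yields two -1 labels; two pair-buckets two labels", {
    set.seed(57)
    bits <- random_bits(4L, 128L)[c(1, 1, 2, 2), ]
    hvs <- pack_rows(bits)
    q <- new("QuantizedSpectrumSet",
             identifier = paste0("s", 1:4),
             precursorMz = c(500.1, 500.12, 900.3, 900.32),
             precursorCharge = rep(2L, 4),
             bins = rep(list(0L), 4), levels = rep(list(1L), 4),
             f = 10L, Q = 16L, params = list())
    a <- runAllBuckets(q, assignBuckets(q), hvs, eps = 0.25)
    expect_equal(sort(unique(a$cluster_label)), c(0L, 1L))
})

test_that("the medoid minimizes summed distance with lowest-ordinal tie-break", {
    set.seed(58)
    center <- random_bits(1L, 256L)[1, ]
    a <- center; a[1:20] <- 1L - a[1:20]
    b <- center; b[100:119] <- 1L - b[100:119]
    hvs <- pack_rows(rbind(a, center, b))
    expect_equal(medoidIndex(hvs), 2L)
    # brute force check
    m <- as.matrix(bucketDistanceMatrix(hvs))
    expect_equal(medoidIndex(hvs), unname(which.min(rowSums(m))))
    # cluster of one is its own representative
    expect_equal(medoidIndex(pack_rows(random_bits(1L, 64L))), 1L)
    # exact tie -> lowest ordinal
    tie <- pack_rows(rbind(center, 1L - center))
    expect_equal(medoidIndex(tie), 1L)
})
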
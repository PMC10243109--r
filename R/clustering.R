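# Per-bucket Hamming distance matrices and clustering.

#' Normalized Hamming distance between packed hypervectors
#'
#' popcount of the XOR of the two bit patterns, divided by D, so the result
#' lies in [0, 1]: 0 for identical vectors, 1 for complements, about 0.5
#' for unrelated random vectors. Operating on packed words reduces the
#' per-pair work from D bit operations to \code{ceiling(D/32)} word
#' operations.
#'
#' @param a,b \linkS4class{PackedHVSet}s of one row each (or row indices
#'   \code{i}, \code{j} into a single set \code{a} when \code{b} is
#'   missing).
#' @param i,j optional row indices.
#' @return numeric distance in [0, 1].
#' @export
hammingDistance <- function(a, b, i = 1L, j = 1L) {
    stopifnot(is(a, "PackedHVSet"))
    if (missing(b)) {
        stopifnot(length(a) >= max(i, j))
        return(cpp_hamming_pair(a@words[i, ], a@words[j, ], a@D))
    }
    stopifnot(is(b, "PackedHVSet"))
    if (a@D != b@D) stop("hypervector dimension mismatch")
    cpp_hamming_pair(a@words[i, ], b@words[j, ], a@D)
}

#' Condensed pairwise distance matrix of a bucket
#'
#' All n(n-1)/2 normalized Hamming distances between the rows of a
#' \linkS4class{PackedHVSet}, returned as a \code{stats::dist} object so it
#' feeds directly into \code{hclust}. Buckets of size 0 or 1 yield an
#' empty/zero-length matrix.
#'
#' @param x a \linkS4class{PackedHVSet}.
#' @return a \code{"dist"} object with \code{Size = length(x)}.
#' @export
bucketDistanceMatrix <- function(x) {
    stopifnot(is(x, "PackedHVSet"))
    n <- length(x)
    d <- cpp_hamming_condensed(x@words, x@D)
    attributes(d) <- list(Size = n, Diag = FALSE, Upper = FALSE,
                          method = "normalized_hamming", class = "dist")
    d
}

#' Bitwise complement of packed hypervectors
#'
#' @param x a \linkS4class{PackedHVSet}.
#' @return a \linkS4class{PackedHVSet} with every valid bit inverted.
#' @export
complementHv <- function(x) {
    stopifnot(is(x, "PackedHVSet"))
    bits <- unpackHvBits(x)
    words <- t(apply(1L - bits, 1L, cpp_pack_bits))
    if (length(x) == 0L) words <- matrix(integer(0), 0L, ncol(x@words))
    new("PackedHVSet", words = words, D = x@D)
}

# Deterministic DBSCAN on a precomputed distance matrix. minPts counts the
# point itself, so minPts = 2 means "at least one neighbor within eps".
# Points are scanned in ascending ordinal order; border points join the
# first core point that reaches them.
.dbscan_precomputed <- function(dm, eps, minPts = 2L) {
    n <- attr(dm, "Size")
    if (n == 0L) return(integer(0))
    if (n == 1L) return(-1L)
    m <- as.matrix(dm)
    nbrs <- lapply(seq_len(n), function(i) which(m[i, ] <= eps & seq_len(n) != i))
    core <- vapply(nbrs, length, integer(1)) + 1L >= minPts
    labels <- rep(NA_integer_, n)
    cl <- -1L
    for (i in seq_len(n)) {
        if (!is.na(labels[i]) || !core[i]) next
        cl <- cl + 1L
        labels[i] <- cl
        queue <- nbrs[[i]]
        while (length(queue)) {
            q <- queue[1L]; queue <- queue[-1L]
            if (is.na(labels[q])) {
                labels[q] <- cl
                if (core[q]) queue <- c(queue, nbrs[[q]][is.na(labels[nbrs[[q]]])])
            } else if (labels[q] == -1L) {
                labels[q] <- cl  # previously noise, reachable border point
            }
        }
    }
    labels[is.na(labels)] <- -1L
    labels
}

#' Cluster one bucket's distance matrix
#'
#' \code{"hierarchical"}: complete-linkage agglomeration cut at height
#' \code{eps}, so every cluster's maximum intra-cluster distance is at most
#' \code{eps}; resulting singletons are relabeled -1 so "clustered" means
#' the same thing under both algorithms. \code{"dbscan"}: density-based
#' clustering on the precomputed matrix with neighborhood radius \code{eps}
#' and minimum neighborhood size \code{minPts} (default 2, the smallest
#' value that lets a pair of spectra form a cluster); noise is -1. Both are
#' deterministic and invariant to input order up to relabeling.
#'
#' @param dm a \code{"dist"} object from [bucketDistanceMatrix()].
#' @param algorithm \code{"hierarchical"} or \code{"dbscan"}.
#' @param eps distance threshold in (0, 1); typical operating range
#'   0.2-0.45, default 0.25.
#' @param minPts DBSCAN minimum neighborhood size (point plus neighbors).
#' @return integer labels, contiguous from 0 within the bucket; -1 marks
#'   noise/singletons.
#' @export
clusterBucket <- function(dm, algorithm = c("hierarchical", "dbscan"),
                          eps = 0.25, minPts = 2L) {
    algorithm <- match.arg(algorithm)
    if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 1)
        stop("eps must lie in (0, 1)")
    n <- attr(dm, "Size")
    if (is.null(n)) stop("dm must be a dist object")
    if (n == 0L) return(integer(0))
    if (n == 1L) return(-1L)
    if (algorithm == "hierarchical") {
        grp <- stats::cutree(stats::hclust(dm, method = "complete"), h = eps)
        sizes <- tabulate(grp)
        labels <- ifelse(sizes[grp] >= 2L, grp, -1L)
    } else {
        labels <- .dbscan_precomputed(dm, eps, minPts)
    }
    # contiguous local labels from 0, in order of first appearance
    pos <- labels >= 0L
    if (any(pos))
        labels[pos] <- match(labels[pos], unique(labels[pos])) - 1L
    as.integer(labels)
}

#' Cluster every bucket and collect global assignments
#'
#' Runs [bucketDistanceMatrix()] and [clusterBucket()] over every bucket of
#' a bucket table, offsetting per-bucket labels so labels are globally
#' unique (no label spans two buckets). Buckets of size 1 yield label -1.
#' Buckets are independent, so the result does not depend on
#' \code{workers}.
#'
#' @param x the \linkS4class{QuantizedSpectrumSet} that was bucketed.
#' @param buckets a bucket table from [assignBuckets()].
#' @param hvs \linkS4class{PackedHVSet} with one row per spectrum of
#'   \code{x}.
#' @param algorithm,eps,minPts passed to [clusterBucket()].
#' @param workers number of processes for per-bucket clustering
#'   (\code{parallel::mclapply}; 1 = serial).
#' @return data.frame with columns \code{identifier},
#'   \code{precursor_charge}, \code{precursor_mz}, \code{bucket} (key
#'   string) and \code{cluster_label}, one row per spectrum of \code{x} in
#'   input order.
#' @export
runAllBuckets <- function(x, buckets, hvs, algorithm = "hierarchical",
                          eps = 0.25, minPts = 2L, workers = 1L) {
    stopifnot(is(x, "QuantizedSpectrumSet"), is(hvs, "PackedHVSet"),
              length(x) == length(hvs))
    n <- length(x)
    label <- rep(-1L, n)
    bucket_key <- rep("-1", n)
    worker <- function(members) {
        if (length(members) < 2L) return(rep(-1L, length(members)))
        clusterBucket(bucketDistanceMatrix(hvs[members]),
                      algorithm = algorithm, eps = eps, minPts = minPts)
    }
    local <- if (workers > 1L)
        parallel::mclapply(buckets, worker, mc.cores = workers)
    else
        lapply(buckets, worker)
    offset <- 0L
    for (k in seq_along(buckets)) {
        members <- buckets[[k]]
        lab <- local[[k]]
        pos <- lab >= 0L
        lab[pos] <- lab[pos] + offset
        offset <- offset + (if (any(pos)) max(lab[pos]) + 1L - offset else 0L)
        label[members] <- lab
        bucket_key[members] <- names(buckets)[k]
    }
    data.frame(identifier = x@identifier,
               precursor_charge = x@precursorCharge,
               precursor_mz = x@precursorMz,
               bucket = bucket_key,
               cluster_label = label,
               stringsAsFactors = FALSE)
}

#' Medoid representative of a cluster
#'
#' The cluster member whose hypervector minimizes the summed normalized
#' Hamming distance to all other members; ties go to the lowest ordinal.
#' This medoid stands in as the cluster's representative spectrum.
#'
#' @param hvs \linkS4class{PackedHVSet} of the cluster members.
#' @return 1-based index of the medoid row.
#' @export
medoidIndex <- function(hvs) {
    stopifnot(is(hvs, "PackedHVSet"), length(hvs) >= 1L)
    n <- length(hvs)
    if (n == 1L) return(1L)
    m <- as.matrix(bucketDistanceMatrix(hvs))
    unname(which.min(rowSums(m)))
}

#' @rdname medoidIndex
#' @param members ordinals of the cluster members.
#' @param spectra the originating \linkS4class{SpectrumSet} (or any object
#'   subsettable by \code{[}).
#' @return \code{representativeSpectrum}: the medoid member of
#'   \code{spectra}.
#' @export
representativeSpectrum <- function(hvs, members, spectra) {
    spectra[members[medoidIndex(hvs[members])]]
}
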
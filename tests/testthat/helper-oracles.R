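# Independent oracles and small fixture builders used across test files.

# random 0/1 matrix, one hypervector per row
random_bits <- function(n, D) {
    matrix(sample(c(0L, 1L), n * D, replace = TRUE), nrow = n)
}

# pack each row of a 0/1 matrix into a PackedHVSet
pack_rows <- function(bits) {
    sets <- lapply(seq_len(nrow(bits)), function(i) packHvBits(bits[i, ]))
    words <- do.call(rbind, lapply(sets, hvWords))
    new("PackedHVSet", words = words, D = ncol(bits))
}

# naive per-bit normalized Hamming distance on raw 0/1 vectors
naive_hamming <- function(a, b) sum(a != b) / length(a)

# brute-force completeness from joint counts, written from the definition:
# 1 - H(C|P)/H(C), natural log, over the supplied cluster/peptide vectors
oracle_completeness <- function(cluster, peptide) {
    n <- length(cluster)
    if (n == 0L) return(1)
    pc <- table(cluster) / n
    h_c <- -sum(pc * log(pc))
    if (h_c == 0) return(1)
    h_cp <- 0
    for (p in unique(peptide)) {
        sel <- peptide == p
        pp <- sum(sel) / n
        cc <- table(cluster[sel]) / sum(sel)
        h_cp <- h_cp + pp * (-sum(cc * log(cc)))
    }
    1 - h_cp / h_c
}

# assignment data.frame from bare label vectors
toy_assignments <- function(labels, ids = as.character(seq_along(labels))) {
    n <- length(labels)
    data.frame(identifier = ids,
               precursor_charge = rep(2L, n),
               precursor_mz = rep(500, n),
               bucket = rep("2:1", n),
               cluster_label = as.integer(labels),
               stringsAsFactors = FALSE)
}

# write a small MGF file from a list of blocks; each block is a list with
# optional title/pepmass/charge and a peaks matrix
write_test_mgf <- function(blocks, path = tempfile(fileext = ".mgf")) {
    lines <- character(0)
    for (b in blocks) {
        lines <- c(lines, "BEGIN IONS")
        if (!is.null(b$title)) lines <- c(lines, paste0("TITLE=", b$title))
        if (!is.null(b$pepmass)) lines <- c(lines, paste0("PEPMASS=", b$pepmass))
        if (!is.null(b$charge)) lines <- c(lines, paste0("CHARGE=", b$charge))
        if (!is.null(b$peaks))
            lines <- c(lines, sprintf("%.6f %.6f", b$peaks[, 1], b$peaks[, 2]))
        lines <- c(lines, "END IONS", "")
    }
    writeLines(lines, path)
    path
}

# peaks matrix helper
pk <- function(mz, intensity) cbind(mz = mz, intensity = intensity)

# compare two label vectors as partitions (invariant to relabeling);
# noise (-1) must match exactly
same_partition <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    if (!all((a == -1L) == (b == -1L))) return(FALSE)
    ok <- a != -1L
    if (!any(ok)) return(TRUE)
    pairs_a <- outer(a[ok], a[ok], "==")
    pairs_b <- outer(b[ok], b[ok], "==")
    all(pairs_a == pairs_b)
}
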
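# Clustering-quality metrics: clustered ratio, incorrect clustering ratio,
# completeness, and the cluster-size histogram.

.cluster_members <- function(assignments) {
    lab <- assignments$cluster_label
    ok <- lab >= 0L
    split(which(ok), lab[ok])
}

#' Clustered spectra ratio
#'
#' Number of spectra in clusters of size >= 2, divided by the total number
#' of input spectra — including spectra rejected during preprocessing, when
#' the assignment table carries them (label -1).
#'
#' @param assignments assignment data.frame (see [runAllBuckets()]); one
#'   row per input spectrum.
#' @return fraction in [0, 1].
#' @export
clusteredRatio <- function(assignments) {
    n <- nrow(assignments)
    if (n == 0L) return(0)
    sizes <- vapply(.cluster_members(assignments), length, integer(1))
    sum(sizes[sizes >= 2L]) / n
}

# joint table of (cluster, peptide) over clustered-and-identified spectra
.joint_counts <- function(assignments, peptideLabels) {
    pep <- peptideLabels[assignments$identifier]
    keep <- assignments$cluster_label >= 0L & !is.na(pep)
    # restrict to clusters that still have >= 2 identified members? No:
    # "clustered" is defined by the assignment (size >= 2 enforced by the
    # clustering step); identification only filters members.
    list(cluster = assignments$cluster_label[keep], peptide = pep[keep])
}

#' Incorrect clustering ratio
#'
#' A clustered-and-identified spectrum is incorrect when its peptide label
#' differs from the most frequent peptide label of its cluster (ties: any
#' maximal label — the incorrect count is the same for every choice). The
#' ratio divides by the number of clustered and identified spectra.
#' Spectra without a peptide label are excluded from both numerator and
#' denominator.
#'
#' @param assignments assignment data.frame.
#' @param peptideLabels named character vector, names = spectrum
#'   identifiers (may cover only a subset).
#' @return fraction in [0, 1]; 0 when nothing is clustered and identified.
#' @export
incorrectRatio <- function(assignments, peptideLabels) {
    jc <- .joint_counts(assignments, peptideLabels)
    if (length(jc$cluster) == 0L) return(0)
    incorrect <- sum(vapply(split(jc$peptide, jc$cluster), function(p) {
        length(p) - max(table(p))
    }, numeric(1)))
    incorrect / length(jc$cluster)
}

#' Clustering completeness
#'
#' \code{1 - H(C | P) / H(C)} over clustered-and-identified spectra, where
#' C is the cluster assignment and P the peptide label and entropies (in
#' nats; the base cancels) come from the empirical joint counts. A result
#' in which every peptide's spectra lie in a single cluster scores 1; when
#' \code{H(C) = 0} (at most one cluster) the score is 1 by convention.
#'
#' @inheritParams incorrectRatio
#' @return value in [0, 1].
#' @export
completenessScore <- function(assignments, peptideLabels) {
    jc <- .joint_counts(assignments, peptideLabels)
    n <- length(jc$cluster)
    if (n == 0L) return(1)
    joint <- table(jc$cluster, jc$peptide) / n
    pc <- rowSums(joint)
    pp <- colSums(joint)
    h_c <- -sum(pc[pc > 0] * log(pc[pc > 0]))
    if (h_c == 0) return(1)
    # H(C|P) = -sum_{c,p} p(c,p) log( p(c,p) / p(p) )
    idx <- joint > 0
    cond <- joint / rep(pp, each = nrow(joint))
    h_c_given_p <- -sum(joint[idx] * log(cond[idx]))
    1 - h_c_given_p / h_c
}

#' Cluster-size histogram
#'
#' Counts clusters (size >= 2) into size bins delimited by \code{edges}:
#' with edges \code{c(5, 500)} the bins are [2, 5], (5, 500], (500, Inf).
#'
#' @param assignments assignment data.frame.
#' @param edges increasing numeric vector of internal bin edges.
#' @return named integer vector of bin counts; the names describe the size
#'   ranges. Sums to the number of clusters.
#' @export
clusterSizeHistogram <- function(assignments, edges = c(5, 10, 50, 100, 500)) {
    sizes <- vapply(.cluster_members(assignments), length, integer(1))
    sizes <- sizes[sizes >= 2L]
    breaks <- c(2 - 1e-9, edges, Inf)
    labels <- c(paste0("2-", edges[1L]),
                if (length(edges) > 1L)
                    paste0(edges[-length(edges)] + 1L, "-", edges[-1L]),
                paste0(">", edges[length(edges)]))
    if (length(sizes) == 0L)
        return(stats::setNames(integer(length(labels)), labels))
    counts <- table(cut(sizes, breaks = breaks, labels = labels))
    stats::setNames(as.integer(counts), labels)
}

#' Full clustering-quality report
#'
#' @param assignments assignment data.frame (one row per input spectrum).
#' @param peptideLabels optional named peptide-label vector; when absent,
#'   the label-dependent metrics are NA.
#' @param edges histogram bin edges, see [clusterSizeHistogram()].
#' @return list with \code{n_total}, \code{n_clustered},
#'   \code{clustered_ratio}, \code{n_incorrect}, \code{incorrect_ratio},
#'   \code{completeness} and \code{cluster_size_histogram}.
#' @export
metricsReport <- function(assignments, peptideLabels = NULL,
                          edges = c(5, 10, 50, 100, 500)) {
    sizes <- vapply(.cluster_members(assignments), length, integer(1))
    n_clustered <- sum(sizes[sizes >= 2L])
    rep <- list(n_total = nrow(assignments),
                n_clustered = as.integer(n_clustered),
                clustered_ratio = clusteredRatio(assignments),
                n_incorrect = NA_integer_,
                incorrect_ratio = NA_real_,
                completeness = NA_real_,
                cluster_size_histogram = as.list(clusterSizeHistogram(assignments, edges)))
    if (!is.null(peptideLabels)) {
        jc <- .joint_counts(assignments, peptideLabels)
        rep$incorrect_ratio <- incorrectRatio(assignments, peptideLabels)
        rep$n_incorrect <- as.integer(round(rep$incorrect_ratio * length(jc$cluster)))
        rep$completeness <- completenessScore(assignments, peptideLabels)
    }
    rep
}
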
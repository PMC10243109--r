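# End-to-end pipeline: preprocess -> bucket -> encode -> distance -> cluster.

#' Pipeline configuration
#'
#' Validated bundle of every knob of the five-step flow. Defaults are the
#' standard operating point: D = 2048 bits, Q = 16 levels, eps = 0.25,
#' complete-linkage hierarchical clustering, charges 2 and 3.
#'
#' @param input MGF file path(s) or a directory.
#' @param output output path for the assignment TSV.
#' @param D hypervector dimension in bits.
#' @param Q intensity quantization levels.
#' @param eps clustering distance threshold in (0, 1).
#' @param algorithm \code{"hierarchical"} or \code{"dbscan"}.
#' @param charges allowed precursor charges.
#' @param minPts DBSCAN minimum neighborhood size.
#' @param preprocess a [preprocessParams()] list (its \code{Q} is
#'   overridden by \code{Q}).
#' @param seed single seed governing codebook and tie-break generation.
#' @param flipId,flipLevel optional codebook flip-count overrides.
#' @param batchSize encoder batch size.
#' @param workers processes for per-bucket clustering (results are
#'   worker-invariant).
#' @param labels optional ground-truth peptide-label TSV for the metrics
#'   report.
#' @param splitByCharge bucket charge states separately.
#' @return named list with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(input, output = NULL, D = 2048L, Q = 16L,
                           eps = 0.25, algorithm = "hierarchical",
                           charges = c(2L, 3L), minPts = 2L,
                           preprocess = preprocessParams(Q = Q),
                           seed = 1L, flipId = NULL, flipLevel = NULL,
                           batchSize = 1024L, workers = 1L,
                           labels = NULL, splitByCharge = TRUE) {
    stopifnot(length(input) >= 1L, D >= 32L, Q >= 2L,
              eps > 0, eps < 1, workers >= 1L)
    algorithm <- match.arg(algorithm, c("hierarchical", "dbscan"))
    if (preprocess$Q != Q)
        preprocess <- do.call(preprocessParams,
                              utils::modifyList(unclass(preprocess)[
                                  setdiff(names(unclass(preprocess)), "f")],
                                  list(Q = Q)))
    cfg <- list(input = input, output = output, D = as.integer(D),
                Q = as.integer(Q), eps = eps, algorithm = algorithm,
                charges = as.integer(charges), minPts = as.integer(minPts),
                preprocess = preprocess, seed = as.integer(seed),
                flipId = flipId, flipLevel = flipLevel,
                batchSize = as.integer(batchSize),
                workers = as.integer(workers), labels = labels,
                splitByCharge = splitByCharge)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full spectral-clustering pipeline
#'
#' Reads MGF input, applies the preprocessing filters, divides spectra into
#' precursor-mass buckets, encodes each retained spectrum into a bit-packed
#' binary hypervector, computes per-bucket normalized Hamming distance
#' matrices and clusters each bucket. The output table has one row per
#' input spectrum (rejected spectra carry bucket \code{"-1"} and label
#' -1). Given the same config and seed the result is identical regardless
#' of \code{workers} or \code{batchSize}.
#'
#' @param config a [pipelineConfig()] list.
#' @param verbose print a per-step summary.
#' @return list with \code{assignments} (data.frame), \code{summary}
#'   (named counts), \code{metrics} ([metricsReport()] output when labels
#'   were supplied, else NULL), and \code{hvs}/\code{quantized} for
#'   downstream use (e.g. [representativeSpectrum()]).
#' @export
runPipeline <- function(config, verbose = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    spectra <- readMgf(config$input, allowedCharges = config$charges)
    counts <- spectrumMetadata(spectra)$counts

    pp <- preprocessSpectra(spectra, config$preprocess)
    quant <- pp$quantized

    assignments <- data.frame(identifier = character(0),
                              precursor_charge = integer(0),
                              precursor_mz = numeric(0),
                              bucket = character(0),
                              cluster_label = integer(0),
                              stringsAsFactors = FALSE)
    n_buckets <- 0L
    hvs <- NULL
    if (length(quant) > 0L) {
        buckets <- assignBuckets(quant, splitByCharge = config$splitByCharge)
        n_buckets <- length(buckets)
        cb <- generateCodebook(D = config$D, f = quant@f, Q = config$Q,
                               seed = config$seed,
                               flipId = if (is.null(config$flipId))
                                   defaultFlip(config$D, quant@f) else config$flipId,
                               flipLevel = if (is.null(config$flipLevel))
                                   defaultFlip(config$D, config$Q) else config$flipLevel)
        hvs <- encodeSpectra(quant, cb, batchSize = config$batchSize)
        assignments <- runAllBuckets(quant, buckets, hvs,
                                     algorithm = config$algorithm,
                                     eps = config$eps, minPts = config$minPts,
                                     workers = config$workers)
    } else if (verbose) {
        message("no spectra survived preprocessing; writing empty outputs")
    }
    # append rejected spectra so every input spectrum appears exactly once
    if (nrow(pp$rejected) > 0L) {
        rej_idx <- match(pp$rejected$identifier, identifiers(spectra))
        assignments <- rbind(assignments,
                             data.frame(identifier = pp$rejected$identifier,
                                        precursor_charge = precursorCharge(spectra)[rej_idx],
                                        precursor_mz = precursorMz(spectra)[rej_idx],
                                        bucket = "-1",
                                        cluster_label = -1L,
                                        stringsAsFactors = FALSE))
    }
    # input order
    assignments <- assignments[match(identifiers(spectra),
                                     assignments$identifier), ]
    rownames(assignments) <- NULL

    if (!is.null(config$output))
        writeAssignments(assignments, config$output)

    labels <- if (!is.null(config$labels)) readPeptideLabels(config$labels)
    metrics <- metricsReport(assignments, labels)
    summary <- c(blocks = unname(counts["blocks"]),
                 read = unname(counts["yielded"]),
                 skipped = unname(counts["skipped"]),
                 charge_filtered = unname(counts["charge_filtered"]),
                 rejected = nrow(pp$rejected),
                 retained = length(quant),
                 buckets = n_buckets,
                 clusters = length(unique(assignments$cluster_label[
                     assignments$cluster_label >= 0L])),
                 clustered = metrics$n_clustered)
    if (verbose) {
        message(paste(sprintf("%s=%s", names(summary), summary),
                      collapse = " "))
        message(sprintf("clustered_ratio=%.4f", metrics$clustered_ratio))
    }
    rejected_tab <- table(pp$rejected$reason)
    list(assignments = assignments, summary = summary,
         rejected_by_rule = rejected_tab,
         metrics = metrics, quantized = quant, hvs = hvs)
}
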
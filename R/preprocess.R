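# Peak/spectrum filtering, intensity normalization and quantization.

#' Preprocessing parameters
#'
#' Bundles the peak- and spectrum-level filter settings with the
#' vectorization grid. The filter defaults follow the standard
#' spectral-clustering regime: remove precursor-related peaks and peaks
#' below 1\% of the base-peak intensity, reject spectra with fewer than 5
#' valid peaks or less than a 250 Da m/z span, retain at most the 50
#' highest-intensity peaks, and L2-normalize intensities. The grid maps
#' fragment m/z in \code{[minMz, maxMz]} to \code{f =
#' ceiling((maxMz - minMz)/binSize)} bins and intensities to \code{Q}
#' quantization levels.
#'
#' @param minPeaks minimum surviving peaks for a spectrum to be kept.
#' @param minMzRange minimum m/z span (Da) between the lowest and highest
#'   surviving peak.
#' @param maxPeaksKept at most this many highest-intensity peaks retained.
#' @param minIntensityFrac peaks below this fraction of the base (largest
#'   surviving) peak are removed.
#' @param precursorRemovalTol peaks within this tolerance (Da) of the
#'   precursor m/z are removed; the default 1.5 Da covers the precursor
#'   isotope envelope at charge >= 2.
#' @param minMz,maxMz fragment m/z window (Da).
#' @param binSize m/z bin width (Da) of the vectorization grid.
#' @param Q number of intensity quantization levels.
#' @return a named list with class \code{"PreprocessParams"}; the derived
#'   bin count is element \code{f}.
#' @examples
#' p <- preprocessParams()
#' p$f  # 27980 bins for the default 101-1500 Da window at 0.05 Da
#' @export
preprocessParams <- function(minPeaks = 5L, minMzRange = 250,
                             maxPeaksKept = 50L, minIntensityFrac = 0.01,
                             precursorRemovalTol = 1.5,
                             minMz = 101.0, maxMz = 1500.0,
                             binSize = 0.05, Q = 16L) {
    stopifnot(minMz < maxMz, binSize > 0, Q >= 2L, minPeaks >= 1L,
              maxPeaksKept >= 1L, minIntensityFrac >= 0,
              precursorRemovalTol >= 0, minMzRange >= 0)
    p <- list(minPeaks = as.integer(minPeaks), minMzRange = minMzRange,
              maxPeaksKept = as.integer(maxPeaksKept),
              minIntensityFrac = minIntensityFrac,
              precursorRemovalTol = precursorRemovalTol,
              minMz = minMz, maxMz = maxMz, binSize = binSize,
              Q = as.integer(Q),
              f = as.integer(ceiling((maxMz - minMz) / binSize)))
    class(p) <- "PreprocessParams"
    p
}

#' Filter and normalize one spectrum
#'
#' Applies the filters in a fixed order: (1) remove peaks within
#' \code{precursorRemovalTol} of the precursor m/z and peaks outside
#' \code{[minMz, maxMz]}; (2) remove peaks below \code{minIntensityFrac}
#' of the largest surviving intensity; (3) reject the spectrum if fewer
#' than \code{minPeaks} peaks survive or their m/z span is below
#' \code{minMzRange}; (4) keep the \code{maxPeaksKept} highest-intensity
#' peaks (ties keep the lower m/z); (5) divide intensities by their
#' Euclidean norm. Rejection is a tagged result, not an error, so callers
#' can tally reasons.
#'
#' @param mz,intensity numeric peak vectors, m/z ascending.
#' @param precursorMz precursor m/z in Da.
#' @param params a [preprocessParams()] list.
#' @return list with \code{status = "ok"} plus normalized \code{mz},
#'   \code{intensity} (sorted by m/z, sum of squared intensities 1), or
#'   \code{status = "rejected"} plus \code{reason} (one of
#'   \code{"too_few_peaks"}, \code{"mz_range_too_small"}).
#' @export
preprocessSpectrum <- function(mz, intensity, precursorMz, params = preprocessParams()) {
    stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
    keep <- abs(mz - precursorMz) > params$precursorRemovalTol &
        mz >= params$minMz & mz <= params$maxMz
    mz <- mz[keep]; intensity <- intensity[keep]
    if (length(mz)) {
        base <- max(intensity)
        keep <- intensity >= params$minIntensityFrac * base
        mz <- mz[keep]; intensity <- intensity[keep]
    }
    if (length(mz) < params$minPeaks)
        return(list(status = "rejected", reason = "too_few_peaks"))
    if (max(mz) - min(mz) < params$minMzRange)
        return(list(status = "rejected", reason = "mz_range_too_small"))
    if (length(mz) > params$maxPeaksKept) {
        # ties broken toward lower m/z: order by intensity desc, then mz asc
        o <- order(-intensity, mz)[seq_len(params$maxPeaksKept)]
        mz <- mz[o]; intensity <- intensity[o]
        o <- order(mz)
        mz <- mz[o]; intensity <- intensity[o]
    }
    intensity <- intensity / sqrt(sum(intensity^2))
    list(status = "ok", mz = mz, intensity = intensity)
}

#' Quantize a normalized spectrum onto the (bin, level) grid
#'
#' Bin index \code{i = floor((mz - minMz)/binSize)} clamped to
#' \code{[0, f - 1]}; level \code{j = min(Q, max(1, ceiling(intensity * Q)))}.
#' When two peaks collide in one bin the higher-intensity peak wins, so
#' each bin contributes exactly one (bin, level) pair to the encoder.
#'
#' @param mz,intensity normalized peak vectors (intensities L2-normalized,
#'   in (0, 1]).
#' @param params a [preprocessParams()] list.
#' @return list with integer vectors \code{bins} (0-based, strictly
#'   increasing) and \code{levels} (in \code{[1, Q]}).
#' @export
quantizeSpectrum <- function(mz, intensity, params = preprocessParams()) {
    stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
    bins <- as.integer(pmin(params$f - 1L,
                            pmax(0L, floor((mz - params$minMz) / params$binSize))))
    levels <- as.integer(pmin(params$Q, pmax(1L, ceiling(intensity * params$Q))))
    # collision rule: keep the highest-intensity peak per bin
    o <- order(bins, -intensity)
    bins <- bins[o]; levels <- levels[o]
    first <- !duplicated(bins)
    list(bins = bins[first], levels = levels[first])
}

#' Preprocess a whole SpectrumSet
#'
#' Runs [preprocessSpectrum()] then [quantizeSpectrum()] over every
#' spectrum, partitioning the input into retained quantized spectra and a
#' rejection table with one first-failing reason per rejected spectrum.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param params a [preprocessParams()] list.
#' @return list with elements \code{quantized}
#'   (\linkS4class{QuantizedSpectrumSet}) and \code{rejected} (data.frame
#'   with columns \code{identifier}, \code{reason}).
#' @export
preprocessSpectra <- function(x, params = preprocessParams()) {
    stopifnot(is(x, "SpectrumSet"))
    n <- length(x)
    keep <- logical(n)
    bins <- vector("list", n); levels <- vector("list", n)
    rej_id <- character(); rej_reason <- character()
    for (i in seq_len(n)) {
        pk <- x@peaks[[i]]
        res <- preprocessSpectrum(pk[, 1L], pk[, 2L], x@precursorMz[i], params)
        if (res$status == "ok") {
            q <- quantizeSpectrum(res$mz, res$intensity, params)
            keep[i] <- TRUE
            bins[[i]] <- q$bins
            levels[[i]] <- q$levels
        } else {
            rej_id <- c(rej_id, x@identifier[i])
            rej_reason <- c(rej_reason, res$reason)
        }
    }
    quant <- new("QuantizedSpectrumSet",
                 identifier = x@identifier[keep],
                 precursorMz = x@precursorMz[keep],
                 precursorCharge = x@precursorCharge[keep],
                 bins = bins[keep], levels = levels[keep],
                 f = params$f, Q = params$Q,
                 params = unclass(params))
    list(quantized = quant,
         rejected = data.frame(identifier = rej_id, reason = rej_reason,
                               stringsAsFactors = FALSE))
}
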
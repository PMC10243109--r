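# Synthetic labeled MGF data with planted cluster structure: templates of
# near-replicate spectra perturbed by m/z jitter, intensity noise, peak
# dropout and spurious peaks.

#' Parameters of the synthetic spectrum generator
#'
#' Each template stands for one peptide: a random peak pattern plus a
#' precursor. Replicates of a template emulate repeated acquisitions of the
#' same analyte — Gaussian m/z jitter (instrument calibration noise),
#' multiplicative log-normal intensity noise (abundance/ionization
#' variation), Bernoulli peak dropout (peaks falling below the detection
#' limit), a few spurious peaks (chemical noise), and a small precursor m/z
#' jitter. With the defaults the precursor jitter is far below the
#' 1.0005079/charge bucket width, so replicates of a template almost always
#' share a precursor-mass bucket; widen \code{precursorJitterSd}
#' deliberately to exercise bucket-boundary losses.
#'
#' @param nTemplates number of templates (distinct synthetic peptides).
#' @param replicatesPerTemplate replicate count, a single value or a
#'   \code{c(min, max)} range sampled per template.
#' @param nPeaksPerTemplate \code{c(min, max)} peaks per template.
#' @param mzRange fragment m/z range (Da) for template peaks.
#' @param precursorMzRange precursor m/z range (Da).
#' @param charges charge states sampled uniformly per template.
#' @param mzJitterSd Gaussian m/z jitter SD (Da) per replicate peak.
#' @param intensityNoiseCv coefficient of variation of the multiplicative
#'   log-normal intensity noise.
#' @param peakDropoutProb per-peak dropout probability per replicate.
#' @param spuriousPeaks \code{c(min, max)} spurious peaks added per
#'   replicate.
#' @param precursorJitterSd Gaussian precursor m/z jitter SD (Da).
#' @param seed integer RNG seed.
#' @return named list with class \code{"FixtureParams"}.
#' @export
fixtureParams <- function(nTemplates = 100L, replicatesPerTemplate = 20L,
                          nPeaksPerTemplate = c(20L, 80L),
                          mzRange = c(101, 1500),
                          precursorMzRange = c(400, 1200),
                          charges = c(2L, 3L),
                          mzJitterSd = 0.01, intensityNoiseCv = 0.2,
                          peakDropoutProb = 0.1, spuriousPeaks = c(0L, 5L),
                          precursorJitterSd = 0.001, seed = 42L) {
    stopifnot(peakDropoutProb >= 0, peakDropoutProb <= 1,
              mzJitterSd >= 0, intensityNoiseCv >= 0, precursorJitterSd >= 0,
              length(nPeaksPerTemplate) == 2L, length(mzRange) == 2L)
    if (length(replicatesPerTemplate) == 1L)
        replicatesPerTemplate <- rep(replicatesPerTemplate, 2L)
    if (length(spuriousPeaks) == 1L)
        spuriousPeaks <- rep(spuriousPeaks, 2L)
    p <- list(nTemplates = as.integer(nTemplates),
              replicatesPerTemplate = as.integer(replicatesPerTemplate),
              nPeaksPerTemplate = as.integer(nPeaksPerTemplate),
              mzRange = mzRange, precursorMzRange = precursorMzRange,
              charges = as.integer(charges),
              mzJitterSd = mzJitterSd, intensityNoiseCv = intensityNoiseCv,
              peakDropoutProb = peakDropoutProb,
              spuriousPeaks = as.integer(spuriousPeaks),
              precursorJitterSd = precursorJitterSd,
              seed = as.integer(seed))
    class(p) <- "FixtureParams"
    p
}

#' Generate spectrum templates
#'
#' One template per synthetic peptide: uniform-random peak m/z in
#' \code{mzRange}, log-normal intensities (meanlog 0, sdlog 1), a precursor
#' m/z uniform in \code{precursorMzRange} and a charge drawn from
#' \code{charges}. Deterministic per seed.
#'
#' @param params a [fixtureParams()] list.
#' @return list of templates, each a list with \code{peptide}, \code{mz},
#'   \code{intensity}, \code{precursorMz}, \code{charge}.
#' @export
generateTemplates <- function(params = fixtureParams()) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(params$seed)
    lapply(seq_len(params$nTemplates), function(k) {
        np <- sample(params$nPeaksPerTemplate[1L]:params$nPeaksPerTemplate[2L], 1L)
        mz <- sort(stats::runif(np, params$mzRange[1L], params$mzRange[2L]))
        list(peptide = sprintf("PEPTIDE_%04d", k),
             mz = mz,
             intensity = stats::rlnorm(np, 0, 1),
             precursorMz = stats::runif(1L, params$precursorMzRange[1L],
                                        params$precursorMzRange[2L]),
             charge = if (length(params$charges) == 1L) params$charges
                      else sample(params$charges, 1L))
    })
}

.perturb_replicate <- function(tmpl, params) {
    keep <- stats::runif(length(tmpl$mz)) >= params$peakDropoutProb
    if (!any(keep)) keep[which.max(tmpl$intensity)] <- TRUE
    mz <- tmpl$mz[keep] + stats::rnorm(sum(keep), 0, params$mzJitterSd)
    sdlog <- sqrt(log(1 + params$intensityNoiseCv^2))
    intensity <- tmpl$intensity[keep] * stats::rlnorm(sum(keep), 0, sdlog)
    nspur <- if (params$spuriousPeaks[2L] > 0L)
        sample(params$spuriousPeaks[1L]:params$spuriousPeaks[2L], 1L) else 0L
    if (nspur > 0L) {
        mz <- c(mz, stats::runif(nspur, params$mzRange[1L], params$mzRange[2L]))
        intensity <- c(intensity, 0.5 * stats::rlnorm(nspur, 0, 1))
    }
    o <- order(mz)
    list(mz = pmax(mz[o], 1e-3), intensity = intensity[o],
         precursorMz = tmpl$precursorMz +
             stats::rnorm(1L, 0, params$precursorJitterSd))
}

#' Write a labeled synthetic MGF dataset
#'
#' Perturbs each template into its replicates, writes them as MGF blocks
#' (TITLE carries the replicate identifier) and writes the ground-truth
#' peptide labels as a TSV usable by the metrics module. Replicate counts
#' are honored exactly; deterministic per the params seed.
#'
#' @param templates output of [generateTemplates()].
#' @param params the same [fixtureParams()] list.
#' @param mgfPath output MGF path.
#' @param labelsPath output TSV path for the ground-truth labels.
#' @return invisibly, a list with \code{n_spectra} and the two paths.
#' @export
generateDataset <- function(templates, params, mgfPath, labelsPath) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old), add = TRUE)
    set.seed(params$seed + 1L)
    blocks <- list()
    ids <- character(0); peps <- character(0)
    for (k in seq_along(templates)) {
        tmpl <- templates[[k]]
        nrep <- if (params$replicatesPerTemplate[1L] ==
                    params$replicatesPerTemplate[2L])
            params$replicatesPerTemplate[1L]
        else sample(params$replicatesPerTemplate[1L]:params$replicatesPerTemplate[2L], 1L)
        rep_ids <- sprintf("%s_rep%03d", tmpl$peptide, seq_len(nrep))
        for (r in seq_len(nrep)) {
            rep_ <- .perturb_replicate(tmpl, params)
            blocks[[length(blocks) + 1L]] <- c(
                "BEGIN IONS",
                paste0("TITLE=", rep_ids[r]),
                sprintf("PEPMASS=%.6f", rep_$precursorMz),
                sprintf("CHARGE=%d+", tmpl$charge),
                sprintf("%.6f %.6f", rep_$mz, rep_$intensity),
                "END IONS", "")
        }
        ids <- c(ids, rep_ids)
        peps <- c(peps, rep(tmpl$peptide, nrep))
    }
    writeLines(unlist(blocks), mgfPath)
    utils::write.table(data.frame(identifier = ids, peptide = peps),
                       labelsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(n_spectra = length(ids), mgf = mgfPath,
                   labels = labelsPath))
}
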
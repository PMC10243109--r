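# MGF reading and assignment-table I/O.

.parse_first_number <- function(x) {
    suppressWarnings(as.numeric(strsplit(trimws(x), "[[:space:]]+")[[1L]][1L]))
}

.parse_charge <- function(x) {
    # accept "2+", "2", "+2"; the first integer in the field wins
    m <- regmatches(x, regexpr("[0-9]+", x))
    if (length(m) == 0L) return(NA_integer_)
    suppressWarnings(as.integer(m))
}

.read_one_mgf <- function(path, allowedCharges) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    begins <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(begins) != length(ends) || any(ends < begins))
        # tolerate a truncated trailing block by pairing what matches
        stop("unbalanced BEGIN IONS/END IONS in ", path)
    stem <- sub("\\.[^.]*$", "", basename(path))

    identifier <- character(); pmz <- numeric(); pch <- integer()
    peaks <- list()
    skipped <- 0L; filtered <- 0L
    for (k in seq_along(begins)) {
        block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
        block <- block[nzchar(block)]
        is_header <- grepl("=", block, fixed = TRUE)
        headers <- block[is_header]
        keys <- toupper(sub("=.*$", "", headers))
        vals <- sub("^[^=]*=", "", headers)

        title <- vals[match("TITLE", keys)]
        pepmass <- vals[match("PEPMASS", keys)]
        charge <- vals[match("CHARGE", keys)]

        mz_val <- if (is.na(pepmass)) NA_real_ else .parse_first_number(pepmass)
        z_val <- if (is.na(charge)) NA_integer_ else .parse_charge(charge)

        peak_lines <- block[!is_header]
        pk <- NULL
        if (length(peak_lines)) {
            tok <- strsplit(peak_lines, "[[:space:]]+")
            mzv <- suppressWarnings(vapply(tok, function(t) as.numeric(t[1L]), numeric(1)))
            inv <- suppressWarnings(vapply(tok, function(t) as.numeric(t[2L]), numeric(1)))
            ok <- is.finite(mzv) & is.finite(inv) & mzv > 0 & inv >= 0
            if (any(ok)) {
                o <- order(mzv[ok])
                pk <- cbind(mz = mzv[ok][o], intensity = inv[ok][o])
            }
        }

        if (is.na(mz_val) || !is.finite(mz_val) || mz_val <= 0 ||
            is.na(z_val) || z_val < 1L || is.null(pk)) {
            skipped <- skipped + 1L
            next
        }
        if (!(z_val %in% allowedCharges)) {
            filtered <- filtered + 1L
            next
        }
        identifier <- c(identifier, if (!is.na(title)) title else
                                        paste0(stem, ":", k))
        pmz <- c(pmz, mz_val)
        pch <- c(pch, z_val)
        peaks[[length(peaks) + 1L]] <- pk
    }
    list(identifier = identifier, precursorMz = pmz, precursorCharge = pch,
         peaks = peaks,
         counts = c(blocks = length(begins),
                    yielded = length(identifier),
                    skipped = skipped, charge_filtered = filtered))
}

#' Read MS/MS spectra from Mascot Generic Format files
#'
#' Parses one or more MGF files (or every \code{*.mgf} file in a directory)
#' into a \linkS4class{SpectrumSet}. Both common charge dialects
#' (\code{CHARGE=2+} and \code{CHARGE=2}) are accepted; the first number of
#' the \code{PEPMASS} line is the precursor m/z (a second number, when
#' present, is an ignored precursor intensity). Peaks are sorted by
#' ascending m/z. Blocks with an unparsable or missing \code{PEPMASS} or
#' \code{CHARGE}, or with zero peaks, are skipped and counted, never fatal;
#' blocks whose charge is not in \code{allowedCharges} are counted as
#' charge-filtered. The identifier is the \code{TITLE} line verbatim when
#' present, otherwise \code{"<file stem>:<block ordinal>"}.
#'
#' @param path character vector of MGF file paths, or a single directory.
#' @param allowedCharges integer vector of precursor charges to retain
#'   (default \code{c(2L, 3L)}, the charge states typically evaluated in
#'   large-scale spectral clustering).
#' @return a \linkS4class{SpectrumSet}; \code{metadata(x)$counts} holds the
#'   named counts \code{blocks}, \code{yielded}, \code{skipped} and
#'   \code{charge_filtered} summed over files.
#' @examples
#' mgf <- tempfile(fileext = ".mgf")
#' writeLines(c("BEGIN IONS", "TITLE=demo.1", "PEPMASS=500.25",
#'              "CHARGE=2+", "150.1 10", "320.6 25", "END IONS"), mgf)
#' readMgf(mgf)
#' @export
readMgf <- function(path, allowedCharges = c(2L, 3L)) {
    if (length(path) == 1L && dir.exists(path))
        path <- sort(list.files(path, pattern = "\\.mgf$", ignore.case = TRUE,
                                full.names = TRUE))
    if (length(path) == 0L)
        stop("no MGF files to read")
    missing <- path[!file.exists(path)]
    if (length(missing))
        stop("MGF file not found: ", paste(missing, collapse = ", "))
    parts <- lapply(path, .read_one_mgf, allowedCharges = as.integer(allowedCharges))
    counts <- Reduce(`+`, lapply(parts, `[[`, "counts"))
    new("SpectrumSet",
        identifier = unlist(lapply(parts, `[[`, "identifier"), use.names = FALSE),
        precursorMz = unlist(lapply(parts, `[[`, "precursorMz"), use.names = FALSE),
        precursorCharge = as.integer(unlist(lapply(parts, `[[`, "precursorCharge"),
                                            use.names = FALSE)),
        peaks = do.call(c, lapply(parts, `[[`, "peaks")),
        metadata = list(files = path, counts = counts))
}

#' Metadata of a SpectrumSet
#' @param x a \linkS4class{SpectrumSet}.
#' @export
spectrumMetadata <- function(x) {
    stopifnot(is(x, "SpectrumSet"))
    x@metadata
}

#' Write and read cluster-assignment tables
#'
#' The assignment table is a tab-separated file with one row per input
#' spectrum (including spectra rejected during preprocessing, which carry
#' bucket \code{"-1"} and cluster label \code{-1}) and header columns
#' \code{identifier}, \code{precursor_charge}, \code{precursor_mz},
#' \code{bucket}, \code{cluster_label}.
#'
#' @param assignments data.frame with the five columns above.
#' @param path output (or input) file path.
#' @return \code{writeAssignments} returns \code{path} invisibly;
#'   \code{readAssignments} returns the data.frame.
#' @export
writeAssignments <- function(assignments, path) {
    need <- c("identifier", "precursor_charge", "precursor_mz",
              "bucket", "cluster_label")
    if (!all(need %in% names(assignments)))
        stop("assignments must contain columns: ", paste(need, collapse = ", "))
    utils::write.table(assignments[, need], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAssignments
#' @export
readAssignments <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = c(identifier = "character",
                                     precursor_charge = "integer",
                                     precursor_mz = "numeric",
                                     bucket = "character",
                                     cluster_label = "integer"),
                      quote = "", comment.char = "")
}

#' Read a peptide-label table
#'
#' Ground-truth identifications used by the clustering-quality metrics: a
#' TSV with header columns \code{identifier} and \code{peptide}.
#'
#' @param path label file path.
#' @return named character vector, names = spectrum identifiers.
#' @export
readPeptideLabels <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character",
                             quote = "", comment.char = "")
    if (!all(c("identifier", "peptide") %in% names(tab)))
        stop("label table must have columns identifier and peptide")
    stats::setNames(tab$peptide, tab$identifier)
}
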
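# MSP input/output and spectrum-level plumbing.
#
# All internal computation uses base-peak-normalized intensities in [0, 1]
# and, by default, integer m/z (peaks merged by intensity sum at ingest).
# MSP files on the 0-999 NIST convention are converted on the way in; the
# writer can emit either the exact relative intensities (default, so that
# write -> read is the identity) or the 0-999 interchange scale.

#' Construct a Spectrum
#'
#' Peaks are sorted by ascending m/z; duplicate m/z values (after no
#' rounding — see [roundPeaks()] for precision control) are merged by
#' intensity summation, conserving total ion signal.
#'
#' @param id unique spectrum identifier.
#' @param mz numeric vector of m/z values (Da), all positive.
#' @param intensity numeric vector of intensities, same length as
#'   \code{mz}, non-negative with a positive maximum.
#' @param name optional compound name.
#' @param smiles optional structure string.
#' @param molMass optional molecular mass in Da.
#' @param source provenance tag (\code{"measured"}, \code{"predicted"},
#'   \code{"synthetic"}).
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum("ex1", mz = c(91, 89), intensity = c(333, 999))
#' peaks(s)
#' @export
Spectrum <- function(id, mz, intensity, name = NA_character_,
                     smiles = NA_character_, molMass = NA_real_,
                     source = "measured") {
    stopifnot(length(mz) == length(intensity))
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
        intensity <- as.numeric(tapply(intensity, factor(mz, unique(mz)), sum))
        mz <- unique(mz)
    }
    p <- cbind(mz = mz, intensity = intensity)
    new("Spectrum", id = as.character(id), name = as.character(name),
        smiles = as.character(smiles), molMass = as.numeric(molMass),
        source = source, peaks = p)
}

#' Normalize a spectrum to its base peak
#'
#' Scales intensities so the base peak (most intense) equals 1. The
#' operation is idempotent and preserves all intensity ratios, which makes
#' downstream weighting exponents scale-free.
#'
#' @param s a [Spectrum-class].
#' @return the normalized [Spectrum-class].
#' @export
normalizeSpectrum <- function(s) {
    stopifnot(is(s, "Spectrum"))
    top <- max(s@peaks[, 2L])
    if (top <= 0) stop("cannot normalize: all intensities are zero")
    if (top == 1) return(s)
    s@peaks[, 2L] <- s@peaks[, 2L] / top
    s
}

#' Round peak m/z to a working precision
#'
#' Rounds m/z to \code{precision} decimal places (0 = unit resolution, the
#' default working precision of the pipeline) and merges peaks that
#' coincide after rounding by summing their intensities.
#'
#' @param s a [Spectrum-class].
#' @param precision decimal places to keep.
#' @return the rounded [Spectrum-class].
#' @export
roundPeaks <- function(s, precision = 0L) {
    stopifnot(is(s, "Spectrum"))
    mz <- round(s@peaks[, 1L], precision)
    Spectrum(s@id, mz, s@peaks[, 2L], name = s@name, smiles = s@smiles,
             molMass = s@molMass, source = s@source)
}

#' Read spectra from a NIST MSP file
#'
#' Records are blank-line separated; each carries a \code{Name} line,
#' optional \code{SMILES}/\code{MW}/\code{DB#}/\code{Comments} lines, a
#' \code{Num Peaks: n} line and then n \code{mz intensity} pairs delimited
#' by whitespace or semicolons (several pairs per line allowed). Records
#' whose peak count disagrees with \code{Num Peaks} are skipped with a
#' warning, never silently dropped. A record without a parseable header is
#' a hard error naming the record index.
#'
#' @param path file path.
#' @param precision decimal places for m/z rounding at ingest (default 0,
#'   unit resolution; \code{NA} keeps m/z values exactly as written).
#' @param normalize base-peak-normalize intensities at ingest (default
#'   \code{TRUE}).
#' @return list of [Spectrum-class] objects.
#' @export
readMsp <- function(path, precision = 0L, normalize = TRUE) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    blank <- grepl("^\\s*$", lines)
    grp <- cumsum(blank) # record index: increments at each blank separator
    groups <- split(lines[!blank], grp[!blank])
    out <- vector("list", length(groups))
    kept <- 0L
    for (i in seq_along(groups)) {
        g <- groups[[i]]
        s <- tryCatch(
            .parseMspRecord(g, i, precision, normalize),
            mspCountMismatch = function(e) {
                warning(conditionMessage(e), call. = FALSE)
                NULL
            }
        )
        if (!is.null(s)) {
            kept <- kept + 1L
            out[[kept]] <- s
        }
    }
    out[seq_len(kept)]
}

.parseMspRecord <- function(g, idx, precision, normalize) {
    isHeader <- grepl("^[A-Za-z#][A-Za-z0-9 _#/-]*:", g)
    headers <- g[isHeader]
    keys <- tolower(trimws(sub(":.*$", "", headers)))
    vals <- trimws(sub("^[^:]*:", "", headers))
    getField <- function(k) {
        j <- match(k, keys)
        if (is.na(j)) NA_character_ else vals[j]
    }
    name <- getField("name")
    np <- getField("num peaks")
    if (is.na(name) || is.na(np) || is.na(suppressWarnings(as.integer(np))))
        stop(sprintf("malformed MSP header in record %d %s", idx,
                     if (is.na(name)) "(missing Name)"
                     else "(missing or invalid 'Num Peaks')"))
    np <- as.integer(np)
    peakLines <- g[!isHeader]
    nums <- suppressWarnings(as.numeric(unlist(
        strsplit(trimws(gsub("[;:,]", " ", paste(peakLines, collapse = " "))),
                 "\\s+")
    )))
    nums <- nums[!is.na(nums)]
    if (length(nums) != 2L * np) {
        cond <- structure(
            class = c("mspCountMismatch", "condition"),
            list(message = sprintf(
                "record %d ('%s'): 'Num Peaks: %d' but %g pairs found; record skipped",
                idx, name, np, length(nums) / 2), call = NULL)
        )
        stop(cond)
    }
    mzv <- nums[seq(1L, length(nums), by = 2L)]
    iv <- nums[seq(2L, length(nums), by = 2L)]
    id <- getField("db#")
    if (is.na(id)) id <- sprintf("%s#%d", name, idx)
    mw <- suppressWarnings(as.numeric(getField("mw")))
    src <- "measured"
    cm <- getField("comments")
    if (!is.na(cm) && grepl("source=", cm))
        src <- sub(".*source=([a-z]+).*", "\\1", cm)
    s <- Spectrum(id, mzv, iv, name = name, smiles = getField("smiles"),
                  molMass = mw, source = src)
    if (!is.na(precision)) s <- roundPeaks(s, precision)
    if (normalize) s <- normalizeSpectrum(s)
    s
}

#' Write spectra to a NIST MSP file
#'
#' Emits one record per spectrum with \code{Name}, \code{DB#} (the
#' spectrum id), optional \code{SMILES} and \code{MW}, a \code{Comments}
#' line carrying the source tag, \code{Num Peaks} and one peak pair per
#' line. With \code{scale = "relative"} (default) intensities are written
#' at full precision so that \code{readMsp(writeMsp(x), precision = NA,}
#' \code{normalize = FALSE)} reproduces them exactly; \code{scale =
#' "nist"} writes rounded 0-999 intensities for interchange with other
#' tools.
#'
#' @param spectra list of [Spectrum-class] objects (may be empty).
#' @param path output file path.
#' @param scale \code{"relative"} or \code{"nist"}.
#' @return invisibly, the path.
#' @export
writeMsp <- function(spectra, path, scale = c("relative", "nist")) {
    scale <- match.arg(scale)
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write: ", path))
    on.exit(close(con))
    for (s in spectra) {
        stopifnot(is(s, "Spectrum"))
        cat(sprintf("Name: %s\n", if (is.na(s@name)) s@id else s@name),
            file = con)
        cat(sprintf("DB#: %s\n", s@id), file = con)
        if (!is.na(s@smiles)) cat(sprintf("SMILES: %s\n", s@smiles), file = con)
        if (!is.na(s@molMass))
            cat(sprintf("MW: %s\n", format(s@molMass, digits = 15)),
                file = con)
        cat(sprintf("Comments: source=%s\n", s@source), file = con)
        p <- s@peaks
        iv <- p[, 2L]
        if (scale == "nist") iv <- round(iv / max(iv) * 999)
        cat(sprintf("Num Peaks: %d\n", nrow(p)), file = con)
        cat(sprintf("%s %s\n", format(p[, 1L], digits = 15, trim = TRUE),
                    format(iv, digits = 15, trim = TRUE)),
            sep = "", file = con)
        cat("\n", file = con)
    }
    invisible(path)
}

#' Read/write spectra in the JSON-lines exchange format
#'
#' One JSON object per line with fields \code{id}, \code{name},
#' \code{smiles}, \code{mol_mass}, \code{source} and \code{peaks} (an
#' array of \code{[mz, intensity]} pairs).
#'
#' @param path file path.
#' @return \code{readSpectraJsonl}: list of [Spectrum-class].
#' @export
readSpectraJsonl <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(ln) {
        x <- jsonlite::fromJSON(ln, simplifyMatrix = TRUE)
        p <- matrix(unlist(x$peaks), ncol = 2L, byrow = !is.matrix(x$peaks))
        if (is.matrix(x$peaks)) p <- x$peaks
        Spectrum(x$id, p[, 1L], p[, 2L],
                 name = x$name %||% NA_character_,
                 smiles = x$smiles %||% NA_character_,
                 molMass = x$mol_mass %||% NA_real_,
                 source = x$source %||% "measured")
    })
}

#' @param spectra list of [Spectrum-class] objects.
#' @rdname readSpectraJsonl
#' @export
writeSpectraJsonl <- function(spectra, path) {
    lines <- vapply(spectra, function(s) {
        jsonlite::toJSON(list(
            id = s@id, name = s@name, smiles = s@smiles,
            mol_mass = s@molMass, source = s@source,
            peaks = unname(s@peaks)
        ), auto_unbox = TRUE, digits = I(17), na = "null")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
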
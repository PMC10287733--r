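# Binned-vector representation and the weighted cosine similarity (WCS)
# baseline, plus the exact brute-force ranker used both as a matching
# method and as the oracle against which the approximate index is judged.

#' Construct a WeightingScheme
#'
#' Defaults follow the Stein-and-Scott family of weighted dot products:
#' intensity exponent 0.5 and m/z exponent 2, unit-width bins up to
#' 1000 Da. Both exponents are configurable.
#'
#' @param intensityPower exponent applied to relative intensity.
#' @param mzPower exponent applied to m/z.
#' @param binWidth bin width in Da.
#' @param maxMz upper m/z bound of the vector.
#' @return a [WeightingScheme-class].
#' @export
WeightingScheme <- function(intensityPower = 0.5, mzPower = 2,
                            binWidth = 1, maxMz = 1000) {
    new("WeightingScheme", intensityPower = intensityPower,
        mzPower = mzPower, binWidth = binWidth, maxMz = maxMz)
}

#' Bin a spectrum into a weighted vector
#'
#' Entry k of the result holds the sum over peaks falling in bin k of
#' \eqn{intensity^a \cdot mz^b}. Bins are half-open \eqn{[k w, (k+1) w)}
#' with 0-based indices; a peak exactly at \code{maxMz} is assigned to the
#' last bin. Peaks beyond \code{maxMz} are dropped and counted in the
#' \code{dropped} slot.
#'
#' @param s a normalized [Spectrum-class].
#' @param scheme a [WeightingScheme-class].
#' @return a [BinnedVector-class].
#' @export
binSpectrum <- function(s, scheme = WeightingScheme()) {
    stopifnot(is(s, "Spectrum"), is(scheme, "WeightingScheme"))
    p <- s@peaks
    m <- as.integer(ceiling(scheme@maxMz / scheme@binWidth))
    keep <- p[, 1L] <= scheme@maxMz
    dropped <- sum(!keep)
    p <- p[keep, , drop = FALSE]
    if (nrow(p) == 0L)
        stop("spectrum '", s@id, "' has no peaks within (0, maxMz]")
    idx <- pmin(floor(p[, 1L] / scheme@binWidth), m - 1L) + 1L
    w <- p[, 2L]^scheme@intensityPower * p[, 1L]^scheme@mzPower
    values <- numeric(m)
    agg <- tapply(w, idx, sum)
    values[as.integer(names(agg))] <- as.numeric(agg)
    new("BinnedVector", values = values, scheme = scheme,
        dropped = as.integer(dropped))
}

#' Bin a list of spectra into a matrix
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param scheme a [WeightingScheme-class].
#' @return numeric matrix, one row per spectrum, rownames = spectrum ids.
#' @export
binSpectra <- function(spectra, scheme = WeightingScheme()) {
    rows <- lapply(spectra, function(s) binSpectrum(s, scheme)@values)
    mat <- do.call(rbind, rows)
    rownames(mat) <- vapply(spectra, spectrumId, character(1))
    mat
}

#' Weighted cosine similarity between two spectra or binned vectors
#'
#' For [BinnedVector-class] inputs, returns
#' \eqn{\langle x, y\rangle / (\|x\| \|y\|)}; both vectors must share a
#' scheme. For [Spectrum-class] inputs, the spectra are binned with
#' \code{scheme} first. The score lies in [0, 1] for nonnegative vectors,
#' is symmetric, equals 1 for proportional vectors, and is invariant to
#' joint scalar scaling.
#'
#' @param x,y [BinnedVector-class] or [Spectrum-class] objects.
#' @param scheme a [WeightingScheme-class], used when x and y are spectra.
#' @return similarity in [0, 1].
#' @export
weightedCosine <- function(x, y, scheme = WeightingScheme()) {
    if (is(x, "Spectrum")) x <- binSpectrum(x, scheme)
    if (is(y, "Spectrum")) y <- binSpectrum(y, scheme)
    stopifnot(is(x, "BinnedVector"), is(y, "BinnedVector"))
    sx <- x@scheme
    sy <- y@scheme
    if (sx@intensityPower != sy@intensityPower ||
        sx@mzPower != sy@mzPower || sx@binWidth != sy@binWidth ||
        sx@maxMz != sy@maxMz)
        stop("weighting schemes of x and y differ")
    .cosine(x@values, y@values)
}

.cosine <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) stop("cosine of a zero vector is undefined")
    sum(a * b) / (na * nb)
}

#' L2-normalize matrix rows
#'
#' @param mat numeric matrix.
#' @return matrix with unit-norm rows.
#' @export
l2normalize <- function(mat) {
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    n <- sqrt(rowSums(mat^2))
    if (any(n == 0)) stop("cannot normalize zero rows")
    mat / n
}

#' Exact top-K ranking by cosine similarity
#'
#' Ranks every library vector against the query by descending cosine
#' similarity (equivalently, ascending squared Euclidean distance after
#' L2 normalization) and returns the top K. Ties are broken by ascending
#' library id for reproducibility.
#'
#' @param q query vector (numeric), or a [BinnedVector-class] /
#'   [SpectralEmbedding-class].
#' @param library numeric matrix of library vectors (rows), with rownames
#'   as ids, or a list of objects of the same class as \code{q}.
#' @param K number of candidates to return.
#' @return candidate data.frame with columns \code{rank}, \code{id},
#'   \code{similarity}, \code{distance} (squared Euclidean between the
#'   L2-normalized vectors, = 2 - 2 cosine); attribute \code{metric} =
#'   \code{"cosine"}.
#' @export
bruteForceRank <- function(q, library, K) {
    if (is(q, "BinnedVector")) q <- q@values
    if (is(q, "SpectralEmbedding")) q <- q@vector
    if (is.list(library)) {
        ids <- vapply(library, function(x)
            if (is(x, "Spectrum")) x@id else NA_character_, character(1))
        library <- do.call(rbind, lapply(library, function(x) {
            if (is(x, "BinnedVector")) x@values
            else if (is(x, "SpectralEmbedding")) x@vector
            else stop("unsupported library element type")
        }))
        if (!any(is.na(ids))) rownames(library) <- ids
    }
    stopifnot(is.matrix(library), nrow(library) >= 1L)
    if (K > nrow(library)) stop("K exceeds library size")
    ids <- rownames(library)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(library)))
    qn <- sqrt(sum(q^2))
    if (qn == 0) stop("query vector is zero")
    ln <- sqrt(rowSums(library^2))
    if (any(ln == 0)) stop("library contains zero vectors")
    sim <- as.numeric(library %*% q) / (ln * qn)
    o <- order(-sim, ids)[seq_len(K)]
    out <- data.frame(
        rank = seq_len(K), id = ids[o], similarity = sim[o],
        distance = 2 - 2 * sim[o], stringsAsFactors = FALSE
    )
    attr(out, "metric") <- "cosine"
    out
}
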
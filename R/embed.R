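# Peak-word embedding: spectra become documents of "Peak@<m/z>" tokens,
# a CBOW (or skip-gram) model is trained on the corpus, and a spectrum is
# embedded by intensity-weighted summation of its peak vectors followed by
# L2 normalization. Because the context window is wider than any document,
# every peak serves as context for every other: an individual EI fragment
# is uninformative, the combination of fragments is what carries
# structure.

#' Construct EmbeddingParams
#'
#' @param dim embedding dimensionality (production default 500).
#' @param window context window size (default 1000, wider than any peak
#'   document by construction).
#' @param architecture \code{"cbow"} (default, observed to work better
#'   for mass spectra) or \code{"skipgram"}.
#' @param negative negative-sampling count.
#' @param lr0 initial learning rate.
#' @param lrDecay learning-rate decrease per epoch.
#' @param epochs training passes.
#' @param minCount minimum corpus frequency for vocabulary membership.
#' @param alpha intensity exponent for document/embedding weights.
#' @param seed RNG seed; training is single-threaded and bit-reproducible
#'   for a fixed seed.
#' @return an [EmbeddingParams-class].
#' @export
EmbeddingParams <- function(dim = 500L, window = 1000L,
                            architecture = c("cbow", "skipgram"),
                            negative = 5L, lr0 = 0.025, lrDecay = 0.00025,
                            epochs = 60L, minCount = 1L, alpha = 0.5,
                            seed = 1L) {
    architecture <- match.arg(architecture)
    new("EmbeddingParams", dim = as.integer(dim), window = as.integer(window),
        architecture = architecture, negative = as.integer(negative),
        lr0 = lr0, lrDecay = lrDecay, epochs = as.integer(epochs),
        minCount = as.integer(minCount), alpha = alpha,
        seed = as.integer(seed))
}

#' Turn a spectrum into a peak-word document
#'
#' Each distinct m/z (rounded to \code{precision} decimal places, merged
#' by intensity sum) becomes one word \code{"Peak@<m/z>"}; a fragment at
#' m/z 89 becomes the word \code{"Peak@89"}. Word order is ascending m/z,
#' though order is irrelevant downstream because peaks have no sequential
#' structure. Weights are \eqn{(I / I_{max})^\alpha}.
#'
#' @param s a [Spectrum-class].
#' @param precision decimal places for m/z rounding.
#' @param alpha intensity exponent for the weights.
#' @return a [PeakDocument-class].
#' @export
spectrumToDocument <- function(s, precision = 0L, alpha = 0.5) {
    stopifnot(is(s, "Spectrum"))
    s <- normalizeSpectrum(roundPeaks(s, precision))
    mzv <- s@peaks[, 1L]
    words <- sprintf("Peak@%.*f", max(0L, precision), mzv)
    new("PeakDocument", words = words,
        weights = unname(s@peaks[, 2L])^alpha)
}

#' Train a peak-word embedding model
#'
#' Builds the vocabulary (words with corpus frequency >= minCount, ordered
#' by decreasing frequency then alphabetically), then trains word vectors
#' with CBOW or skip-gram plus negative sampling in a single deterministic
#' thread. The learning rate is constant within an epoch and decreases by
#' \code{lrDecay} after each epoch.
#'
#' @param corpus list of [PeakDocument-class] objects.
#' @param params an [EmbeddingParams-class].
#' @return a [PeakEmbeddingModel-class].
#' @export
trainEmbeddingModel <- function(corpus, params = EmbeddingParams()) {
    if (length(corpus) == 0L) stop("training corpus is empty")
    stopifnot(is(params, "EmbeddingParams"))
    docs <- lapply(corpus, function(d) d@words)
    tab <- table(unlist(docs))
    tab <- tab[tab >= params@minCount]
    if (length(tab) == 0L)
        stop("no words reach minCount = ", params@minCount)
    vocab <- names(tab)[order(-as.integer(tab), names(tab))]
    freq <- as.numeric(tab[vocab])
    idx <- lapply(docs, function(w) {
        i <- match(w, vocab)
        as.integer(i[!is.na(i)]) - 1L
    })
    vec <- .w2v_train(idx, freq, params@dim, params@window,
                      params@architecture == "cbow", params@negative,
                      params@lr0, params@lrDecay, params@epochs,
                      as.double(params@seed))
    rownames(vec) <- vocab
    new("PeakEmbeddingModel", vectors = vec, params = params,
        corpusFingerprint = .corpusFingerprint(docs))
}

.corpusFingerprint <- function(docs) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(vapply(docs, paste, character(1), collapse = " "), tmp)
    unname(tools::md5sum(tmp))
}

#' Embed a spectrum with a trained model
#'
#' The embedding is \eqn{\sum_i w_i v(word_i)} over the spectrum's peak
#' words, with intensity weights \eqn{w_i = (I_i/I_{max})^\alpha} taken
#' from the model's alpha, optionally followed by L2 normalization
#' (default), so that squared Euclidean distance between embeddings orders
#' identically to cosine similarity. Out-of-vocabulary words are skipped
#' and counted in the \code{oov} slot; a spectrum whose words are all
#' out-of-vocabulary is an error.
#'
#' @param s a [Spectrum-class].
#' @param model a [PeakEmbeddingModel-class].
#' @param normalize L2-normalize the embedding (default \code{TRUE}).
#' @return a [SpectralEmbedding-class].
#' @export
embedSpectrum <- function(s, model, normalize = TRUE) {
    stopifnot(is(s, "Spectrum"), is(model, "PeakEmbeddingModel"))
    doc <- spectrumToDocument(s, precision = 0L, alpha = model@params@alpha)
    hit <- doc@words %in% rownames(model@vectors)
    if (!any(hit))
        stop("all peak words of spectrum '", s@id,
             "' are out of vocabulary")
    w <- doc@weights[hit]
    v <- model@vectors[doc@words[hit], , drop = FALSE]
    vec <- as.numeric(crossprod(v, w))
    if (normalize) {
        n <- sqrt(sum(vec^2))
        if (n == 0) stop("zero embedding for spectrum '", s@id, "'")
        vec <- vec / n
    }
    new("SpectralEmbedding", vector = vec, normalized = normalize,
        oov = as.integer(sum(!hit)))
}

#' Embed a list of spectra into a matrix
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param model a [PeakEmbeddingModel-class].
#' @param normalize L2-normalize rows (default \code{TRUE}).
#' @return numeric matrix, one row per spectrum, rownames = ids.
#' @export
embedSpectra <- function(spectra, model, normalize = TRUE) {
    rows <- lapply(spectra, function(s)
        embedSpectrum(s, model, normalize)@vector)
    mat <- do.call(rbind, rows)
    rownames(mat) <- vapply(spectra, spectrumId, character(1))
    mat
}

#' Save / load an embedding model
#'
#' The model is persisted as a single JSON file holding the
#' hyperparameters, the corpus fingerprint, the vocabulary and the word
#' vectors at full precision; loading requires no retraining.
#'
#' @param model a [PeakEmbeddingModel-class].
#' @param path file path.
#' @return \code{loadEmbeddingModel}: the restored model.
#' @export
saveEmbeddingModel <- function(model, path) {
    p <- model@params
    obj <- list(
        format = "eimatch-w2v-1",
        params = list(dim = p@dim, window = p@window,
                      architecture = p@architecture, negative = p@negative,
                      lr0 = p@lr0, lrDecay = p@lrDecay, epochs = p@epochs,
                      minCount = p@minCount, alpha = p@alpha, seed = p@seed),
        corpusFingerprint = model@corpusFingerprint,
        words = rownames(model@vectors),
        vectors = unname(model@vectors)
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
    invisible(path)
}

#' @rdname saveEmbeddingModel
#' @export
loadEmbeddingModel <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    obj <- jsonlite::fromJSON(readLines(path, warn = FALSE))
    if (is.null(obj$format) || obj$format != "eimatch-w2v-1")
        stop("not an eimatch embedding model file (or wrong version): ", path)
    p <- obj$params
    params <- EmbeddingParams(dim = p$dim, window = p$window,
                              architecture = p$architecture,
                              negative = p$negative, lr0 = p$lr0,
                              lrDecay = p$lrDecay, epochs = p$epochs,
                              minCount = p$minCount, alpha = p$alpha,
                              seed = p$seed)
    vec <- obj$vectors
    rownames(vec) <- obj$words
    new("PeakEmbeddingModel", vectors = vec, params = params,
        corpusFingerprint = obj$corpusFingerprint)
}
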
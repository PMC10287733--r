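# End-to-end matching pipeline: build library artifacts, query them with
# any of the four representation x search variants, apply the molecular
# mass filter, compute recall@k, and expand a library incrementally.

#' Construct a MethodVariant
#'
#' Either give the two axes explicitly or one of the shorthand labels:
#' \code{"wcs"} (binned + brute), \code{"ec"} (embedding + brute),
#' \code{"bh"} (binned + hnsw), \code{"fastei"} (embedding + hnsw).
#'
#' @param representation \code{"binned"} or \code{"embedding"}, or a
#'   shorthand label.
#' @param search \code{"brute"} or \code{"hnsw"}.
#' @return a [MethodVariant-class].
#' @export
methodVariant <- function(representation, search = NULL) {
    if (is.null(search)) {
        lab <- match.arg(representation, c("wcs", "ec", "bh", "fastei"))
        representation <- switch(lab, wcs = "binned", bh = "binned",
                                 ec = "embedding", fastei = "embedding")
        search <- switch(lab, wcs = "brute", ec = "brute",
                         bh = "hnsw", fastei = "hnsw")
    }
    new("MethodVariant", representation = representation, search = search)
}

#' @rdname methodVariant
#' @param x a [MethodVariant-class].
#' @export
variantLabel <- function(x) {
    if (x@representation == "binned")
        if (x@search == "brute") "wcs" else "bh"
    else
        if (x@search == "brute") "ec" else "fastei"
}

#' Build library artifacts for matching
#'
#' Materializes the binned matrix (always), the embedding matrix (when a
#' model is given), and — for hnsw-search variants — an HNSW index over
#' the variant's representation. Binned rows are L2-normalized before
#' indexing so that squared Euclidean distance in the index orders like
#' cosine similarity; embeddings are L2-normalized by construction.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param model a [PeakEmbeddingModel-class], or \code{NULL} for
#'   binned-only variants.
#' @param scheme a [WeightingScheme-class].
#' @param hnswParams an [HNSWParams-class] (used when the variant
#'   searches with hnsw).
#' @param variant default [MethodVariant-class] for queries.
#' @param keyMap named character, spectrum id -> molecule canonical key;
#'   defaults to the spectrum ids themselves.
#' @param massMap named numeric, spectrum id -> molecular mass; defaults
#'   to the spectra's \code{molMass} metadata.
#' @return a [LibraryArtifacts-class].
#' @export
buildArtifacts <- function(spectra, model = NULL,
                           scheme = WeightingScheme(),
                           hnswParams = HNSWParams(),
                           variant = methodVariant("fastei"),
                           keyMap = NULL, massMap = NULL) {
    if (length(spectra) == 0L) stop("library must contain spectra")
    ids <- vapply(spectra, spectrumId, character(1))
    if (anyDuplicated(ids)) stop("duplicate spectrum ids in library")
    if (variant@representation == "embedding" && is.null(model))
        stop("embedding variants require a trained model")
    binned <- binSpectra(spectra, scheme)
    embeddings <- if (!is.null(model)) embedSpectra(spectra, model) else NULL
    if (is.null(keyMap)) keyMap <- setNames(ids, ids)
    if (is.null(massMap))
        massMap <- setNames(vapply(spectra, molMass, numeric(1)), ids)
    index <- NULL
    if (variant@search == "hnsw") {
        rep <- if (variant@representation == "embedding") embeddings
               else l2normalize(binned)
        index <- hnswIndex(ncol(rep), hnswParams)
        hnswInsert(index, rep, ids)
    }
    new("LibraryArtifacts", spectra = spectra, binned = binned,
        embeddings = embeddings, index = index, idMap = ids,
        keyMap = keyMap, massMap = massMap, scheme = scheme,
        model = model, variant = variant)
}

#' Query a library with one spectrum
#'
#' Brute variants return the exact top-K by cosine similarity; hnsw
#' variants return the approximate top-K from the index. Whatever the
#' internal metric, the output carries cosine similarity. Candidates are
#' annotated with their molecule key and molecular mass.
#'
#' @param q a [Spectrum-class].
#' @param artifacts a [LibraryArtifacts-class].
#' @param K candidates to return (must not exceed the library size).
#' @param variant a [MethodVariant-class]; defaults to the artifacts'.
#' @param ef hnsw search width (default: max(K, index ef)).
#' @return candidate data.frame with columns \code{rank}, \code{id},
#'   \code{key}, \code{similarity}, \code{distance}, \code{molMass}.
#' @export
searchLibrary <- function(q, artifacts, K = 100L,
                          variant = artifacts@variant, ef = NULL) {
    stopifnot(is(q, "Spectrum"), is(artifacts, "LibraryArtifacts"))
    n <- length(artifacts@spectra)
    if (K > n) stop("K exceeds library size")
    qvec <- if (variant@representation == "embedding") {
        if (is.null(artifacts@model))
            stop("artifacts carry no embedding model")
        embedSpectrum(q, artifacts@model)@vector
    } else {
        binSpectrum(q, artifacts@scheme)@values
    }
    if (variant@search == "brute") {
        mat <- if (variant@representation == "embedding")
            artifacts@embeddings else artifacts@binned
        cand <- bruteForceRank(qvec, mat, K)
    } else {
        if (is.null(artifacts@index))
            stop("artifacts carry no HNSW index; rebuild with an hnsw variant")
        if (variant@representation != artifacts@variant@representation)
            stop("index was built over the ",
                 artifacts@variant@representation,
                 " representation; cannot serve an hnsw search on ",
                 variant@representation, " vectors")
        qn <- qvec / sqrt(sum(qvec^2))
        ef <- if (is.null(ef)) max(K, artifacts@index@params@ef) else ef
        cand <- hnswSearch(artifacts@index, qn, K, ef)
    }
    cand$key <- unname(artifacts@keyMap[cand$id])
    cand$molMass <- unname(artifacts@massMap[cand$id])
    cand
}

#' Filter candidates by molecular mass
#'
#' Keeps candidates whose molecular mass is within \code{tol} Da
#' (inclusive) of the query molecule's mass, preserving their relative
#' order; ranks are re-assigned positionally among the survivors.
#' Candidates lacking a mass are excluded and counted in the
#' \code{missingMass} attribute rather than raising an error.
#'
#' @param cand candidate data.frame from [searchLibrary()].
#' @param queryMass query molecule's mass in Da.
#' @param tol tolerance in Da (default 5; \code{Inf} = identity).
#' @return the filtered candidate data.frame.
#' @export
massFilter <- function(cand, queryMass, tol = 5) {
    stopifnot(tol >= 0)
    if (is.null(cand$molMass)) stop("candidates carry no molMass column")
    known <- !is.na(cand$molMass)
    keep <- known & abs(cand$molMass - queryMass) <= tol
    out <- cand[keep, , drop = FALSE]
    if (nrow(out)) out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    attr(out, "metric") <- attr(cand, "metric")
    attr(out, "missingMass") <- sum(!known)
    out
}

#' Recall at k over a set of queries
#'
#' recall@k is the fraction of queries whose true molecule key appears
#' among the distinct molecule keys of the top-k candidates. Truth is
#' matched on molecule keys, not spectrum ids, so replicate spectra of
#' one molecule count as correct. Queries whose truth key is absent from
#' the library's key map are excluded with a warning and counted
#' separately.
#'
#' @param results named list (query id -> candidate data.frame).
#' @param truth named character (query id -> molecule canonical key).
#' @param ks integer vector of k values.
#' @param libraryKeys keys present in the library; defaults to the union
#'   of candidate keys (pass \code{artifacts@keyMap} for strictness).
#' @param variant [MethodVariant-class] recorded in the result.
#' @param massFilterDa mass-filter tolerance recorded in the result.
#' @return an [EvalResult-class].
#' @export
recallAtK <- function(results, truth, ks = c(1L, 10L), libraryKeys = NULL,
                      variant = methodVariant("wcs"),
                      massFilterDa = NA_real_) {
    stopifnot(length(results) > 0L, !is.null(names(results)))
    qids <- names(results)
    if (!all(qids %in% names(truth)))
        stop("every query needs a truth key")
    tkeys <- truth[qids]
    if (!is.null(libraryKeys)) {
        covered <- tkeys %in% libraryKeys
        if (any(!covered))
            warning(sum(!covered),
                    " queries excluded: truth key not in library")
    } else {
        covered <- rep(TRUE, length(qids))
    }
    excluded <- sum(!covered)
    qids <- qids[covered]
    tkeys <- tkeys[covered]
    if (length(qids) == 0L) stop("no queries with library-covered truth")
    ks <- sort(unique(as.integer(ks)))
    hitRank <- vapply(seq_along(qids), function(i) {
        keys <- results[[qids[i]]]$key
        j <- match(tkeys[i], keys)
        if (is.na(j)) Inf else j
    }, numeric(1))
    perK <- vapply(ks, function(k) mean(hitRank <= k), numeric(1))
    names(perK) <- ks
    new("EvalResult", perK = perK, nQueries = length(qids),
        excluded = as.integer(excluded), variant = variant,
        massFilterDa = massFilterDa)
}

#' Evaluate a matching variant on a query set
#'
#' Runs [searchLibrary()] for every query, optionally applies the mass
#' filter (using each query's own metadata mass), and summarizes
#' recall@k.
#'
#' @param queries list of [Spectrum-class] query spectra.
#' @param artifacts a [LibraryArtifacts-class].
#' @param truth named character (query id -> molecule key).
#' @param ks k values for recall.
#' @param K candidates retrieved per query before filtering.
#' @param variant a [MethodVariant-class].
#' @param massFilterDa mass-filter tolerance in Da (\code{NA} = none).
#' @param ef hnsw search width override.
#' @return an [EvalResult-class]; the per-query candidate lists are
#'   attached as attribute \code{"results"}.
#' @export
evaluateMatching <- function(queries, artifacts, truth, ks = c(1L, 10L),
                             K = 100L, variant = artifacts@variant,
                             massFilterDa = NA_real_, ef = NULL) {
    res <- lapply(queries, function(q) {
        cand <- searchLibrary(q, artifacts, K = K, variant = variant,
                              ef = ef)
        if (!is.na(massFilterDa)) {
            qm <- molMass(q)
            if (!is.na(qm)) cand <- massFilter(cand, qm, massFilterDa)
        }
        cand
    })
    names(res) <- vapply(queries, spectrumId, character(1))
    ev <- recallAtK(res, truth, ks, libraryKeys = artifacts@keyMap,
                    variant = variant, massFilterDa = massFilterDa)
    attr(ev, "results") <- res
    ev
}

#' Expand a library incrementally
#'
#' Appends new spectra to the artifacts and inserts their vectors into
#' the existing HNSW index without any rebuild; prior entries are
#' untouched. New ids must be disjoint from existing ones.
#'
#' @param artifacts a [LibraryArtifacts-class].
#' @param newSpectra list of [Spectrum-class] objects (may be empty).
#' @param keyMap named character for the new ids (default: identity).
#' @param massMap named numeric for the new ids (default: metadata).
#' @return the expanded [LibraryArtifacts-class].
#' @export
expandLibrary <- function(artifacts, newSpectra, keyMap = NULL,
                          massMap = NULL) {
    stopifnot(is(artifacts, "LibraryArtifacts"))
    if (length(newSpectra) == 0L) return(artifacts)
    newIds <- vapply(newSpectra, spectrumId, character(1))
    if (any(newIds %in% artifacts@idMap))
        stop("duplicate ids: ", paste(intersect(newIds, artifacts@idMap),
                                      collapse = ", "))
    binned <- binSpectra(newSpectra, artifacts@scheme)
    embeddings <- if (!is.null(artifacts@model))
        embedSpectra(newSpectra, artifacts@model) else NULL
    if (is.null(keyMap)) keyMap <- setNames(newIds, newIds)
    if (is.null(massMap))
        massMap <- setNames(vapply(newSpectra, molMass, numeric(1)), newIds)
    if (!is.null(artifacts@index)) {
        rep <- if (artifacts@variant@representation == "embedding")
            embeddings else l2normalize(binned)
        hnswInsert(artifacts@index, rep, newIds)
    }
    new("LibraryArtifacts",
        spectra = c(artifacts@spectra, newSpectra),
        binned = rbind(artifacts@binned, binned),
        embeddings = if (is.null(artifacts@embeddings)) NULL
                     else rbind(artifacts@embeddings, embeddings),
        index = artifacts@index,
        idMap = c(artifacts@idMap, newIds),
        keyMap = c(artifacts@keyMap, keyMap),
        massMap = c(artifacts@massMap, massMap),
        scheme = artifacts@scheme, model = artifacts@model,
        variant = artifacts@variant)
}
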
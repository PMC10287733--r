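# S4 classes for the whole pipeline. Validity methods enforce the
# contracts that every downstream stage relies on (sorted unique peaks,
# positive base peak, matching dimensions), so malformed objects fail at
# construction rather than deep inside a search.

#' Spectrum: a peak list with molecule metadata
#'
#' The universal currency of the pipeline: an ordered peak list
#' (m/z, relative intensity) plus optional compound name, SMILES and
#' molecular mass. Peaks are stored as a two-column numeric matrix with
#' columns \code{mz} and \code{intensity}, sorted by ascending m/z with no
#' duplicate m/z values.
#'
#' @slot id unique spectrum identifier.
#' @slot name compound name (\code{NA} if unknown).
#' @slot smiles structure string (\code{NA} if unknown).
#' @slot molMass molecular mass in Da (\code{NA} if unknown).
#' @slot source provenance tag, e.g. \code{"measured"}, \code{"predicted"}
#'   or \code{"synthetic"}.
#' @slot peaks two-column numeric matrix (\code{mz}, \code{intensity}).
#'
#' @seealso [Spectrum()] for the user constructor, [readMsp()],
#'   [normalizeSpectrum()]
#' @exportClass Spectrum
setClass("Spectrum",
    representation(
        id = "character",
        name = "character",
        smiles = "character",
        molMass = "numeric",
        source = "character",
        peaks = "matrix"
    ),
    prototype(
        name = NA_character_, smiles = NA_character_,
        molMass = NA_real_, source = "measured"
    )
)

setValidity("Spectrum", function(object) {
    p <- object@peaks
    if (!is.numeric(p) || ncol(p) != 2L)
        return("peaks must be a numeric matrix with columns mz, intensity")
    if (nrow(p) < 1L)
        return("a spectrum must contain at least one peak")
    mz <- p[, 1L]
    int <- p[, 2L]
    if (any(!is.finite(mz)) || any(!is.finite(int)))
        return("non-finite m/z or intensity")
    if (any(mz <= 0))
        return("all m/z values must be positive")
    if (any(int < 0))
        return("intensities must be non-negative")
    if (max(int) <= 0)
        return("maximum intensity must be positive")
    if (is.unsorted(mz, strictly = TRUE))
        return("peaks must be sorted by strictly ascending m/z (no duplicates)")
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        return("id must be a single non-empty string")
    TRUE
})

#' Weighting scheme for binned spectrum vectors
#'
#' Parameters of the classical binned representation: each bin holds the
#' sum over its peaks of \eqn{intensity^a \cdot mz^b}. Bins are half-open
#' intervals \eqn{[k w, (k+1) w)} with 0-based indices; a peak exactly at
#' \code{maxMz} falls into the last bin.
#'
#' @slot intensityPower exponent \eqn{a} applied to relative intensity.
#' @slot mzPower exponent \eqn{b} applied to m/z.
#' @slot binWidth bin width in Da.
#' @slot maxMz upper m/z bound of the vector (default 1000 Da, matching
#'   the molecular-mass cutoff of the library filters).
#' @exportClass WeightingScheme
setClass("WeightingScheme",
    representation(
        intensityPower = "numeric",
        mzPower = "numeric",
        binWidth = "numeric",
        maxMz = "numeric"
    )
)

setValidity("WeightingScheme", function(object) {
    if (object@binWidth <= 0) return("binWidth must be > 0")
    if (object@maxMz <= 0) return("maxMz must be > 0")
    TRUE
})

#' Binned vector representation of a spectrum
#'
#' @slot values weighted intensities, length \code{ceiling(maxMz/binWidth)}.
#' @slot scheme the [WeightingScheme-class] used.
#' @slot dropped number of peaks beyond \code{maxMz} that were dropped.
#' @exportClass BinnedVector
setClass("BinnedVector",
    representation(
        values = "numeric",
        scheme = "WeightingScheme",
        dropped = "integer"
    ),
    prototype(dropped = 0L)
)

setValidity("BinnedVector", function(object) {
    m <- ceiling(object@scheme@maxMz / object@scheme@binWidth)
    if (length(object@values) != m)
        return(sprintf("values must have length %d for this scheme", m))
    if (any(object@values < 0)) return("all entries must be >= 0")
    if (all(object@values == 0)) return("binned vector must not be all zero")
    TRUE
})

#' Peak-word document derived from a spectrum
#'
#' Tokenized form of a spectrum for embedding training: one word
#' \code{"Peak@<m/z>"} per distinct rounded m/z, with intensity-derived
#' weights.
#'
#' @slot words token strings, ascending m/z order.
#' @slot weights positive per-word weights, same length as \code{words}.
#' @exportClass PeakDocument
setClass("PeakDocument",
    representation(words = "character", weights = "numeric")
)

setValidity("PeakDocument", function(object) {
    if (length(object@words) != length(object@weights))
        return("words and weights must have the same length")
    if (length(object@words) < 1L) return("document must not be empty")
    if (anyDuplicated(object@words)) return("words must be unique")
    if (any(object@weights <= 0)) return("weights must be positive")
    TRUE
})

#' Hyperparameters of the peak-word embedding model
#'
#' Defaults are the production settings used for million-scale corpora:
#' 500-dimensional vectors, CBOW architecture, window 1000 (wider than any
#' peak document, so every peak is context for every other), 5 negative
#' samples, initial learning rate 0.025 decaying by 0.00025 per epoch,
#' 60 epochs.
#'
#' @slot dim embedding dimensionality.
#' @slot window context window size.
#' @slot architecture \code{"cbow"} or \code{"skipgram"}.
#' @slot negative number of negative samples per target.
#' @slot lr0 initial learning rate.
#' @slot lrDecay learning-rate decrease per epoch.
#' @slot epochs training passes over the corpus.
#' @slot minCount minimum corpus frequency for a word to enter the
#'   vocabulary.
#' @slot alpha intensity exponent used for document and embedding weights.
#' @slot seed RNG seed for weight initialization and negative sampling.
#' @exportClass EmbeddingParams
setClass("EmbeddingParams",
    representation(
        dim = "integer", window = "integer", architecture = "character",
        negative = "integer", lr0 = "numeric", lrDecay = "numeric",
        epochs = "integer", minCount = "integer", alpha = "numeric",
        seed = "integer"
    )
)

setValidity("EmbeddingParams", function(object) {
    if (object@dim < 1L) return("dim must be >= 1")
    if (object@window < 1L) return("window must be >= 1")
    if (!object@architecture %in% c("cbow", "skipgram"))
        return("architecture must be 'cbow' or 'skipgram'")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@negative < 1L) return("negative must be >= 1")
    if (object@minCount < 1L) return("minCount must be >= 1")
    TRUE
})

#' Trained peak-word embedding model
#'
#' @slot vectors numeric matrix, one row per vocabulary word (rownames are
#'   the words), \code{dim} columns.
#' @slot params the [EmbeddingParams-class] used for training.
#' @slot corpusFingerprint md5 fingerprint of the training corpus.
#' @exportClass PeakEmbeddingModel
setClass("PeakEmbeddingModel",
    representation(
        vectors = "matrix",
        params = "EmbeddingParams",
        corpusFingerprint = "character"
    )
)

setValidity("PeakEmbeddingModel", function(object) {
    if (nrow(object@vectors) < 1L)
        return("vocabulary must be non-empty")
    if (ncol(object@vectors) != object@params@dim)
        return("vector width must equal params dim")
    if (is.null(rownames(object@vectors)))
        return("vectors must have words as rownames")
    TRUE
})

#' Spectral embedding of one spectrum
#'
#' @slot vector length-\code{dim} numeric vector.
#' @slot normalized whether the vector is L2-normalized.
#' @slot oov number of out-of-vocabulary peak words skipped.
#' @exportClass SpectralEmbedding
setClass("SpectralEmbedding",
    representation(vector = "numeric", normalized = "logical",
                   oov = "integer"),
    prototype(normalized = TRUE, oov = 0L)
)

setValidity("SpectralEmbedding", function(object) {
    if (length(object@vector) < 1L) return("vector must be non-empty")
    if (object@normalized) {
        n <- sqrt(sum(object@vector^2))
        if (abs(n - 1) > 1e-9)
            return("normalized embedding must have unit L2 norm")
    }
    TRUE
})

#' HNSW index parameters
#'
#' Defaults are the production settings for million-scale libraries of
#' 500-dimensional embeddings: \code{M = 64}, \code{efConstruction = 600},
#' \code{ef = 300}. The level multiplier defaults to the standard
#' \code{mL = 1/log(M)}; layer 0 allows \code{2 M} links per node.
#'
#' @slot M maximum bidirectional links per node per layer (layer 0 allows
#'   \code{2*M}).
#' @slot efConstruction dynamic candidate-list size during insertion.
#' @slot ef dynamic candidate-list size during search.
#' @slot mL level-generation multiplier of the exponential level law.
#' @slot seed RNG seed for level assignment.
#' @slot heuristic use the spread-preserving neighbour-selection heuristic
#'   (\code{TRUE}) or plain closest-M selection (\code{FALSE}).
#' @exportClass HNSWParams
setClass("HNSWParams",
    representation(
        M = "integer", efConstruction = "integer", ef = "integer",
        mL = "numeric", seed = "integer", heuristic = "logical"
    )
)

setValidity("HNSWParams", function(object) {
    if (object@M < 2L) return("M must be >= 2")
    if (object@efConstruction < object@M)
        return("efConstruction must be >= M")
    if (object@ef < 1L) return("ef must be >= 1")
    if (!(object@mL > 0)) return("mL must be > 0")
    TRUE
})

#' HNSW approximate nearest-neighbour index
#'
#' A handle on the in-memory multi-layer proximity graph. The graph lives
#' in native code and is mutated in place by [hnswInsert()]; use
#' [hnswSave()] / [hnswLoad()] for persistence and [hnswGraph()] to dump
#' the adjacency structure for audits.
#'
#' @slot ptr external pointer to the native index.
#' @slot dim vector dimensionality.
#' @slot params the [HNSWParams-class] used at creation.
#' @exportClass HNSWIndex
setClass("HNSWIndex",
    representation(ptr = "externalptr", dim = "integer",
                   params = "HNSWParams")
)

setClassUnion("HNSWIndexOrNULL", c("HNSWIndex", "NULL"))
setClassUnion("PeakEmbeddingModelOrNULL", c("PeakEmbeddingModel", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Method variant: representation x search strategy
#'
#' The four combinations reproduce the standard ablation: weighted binning
#' + exact cosine (WCS), embeddings + exact cosine (EC), weighted binning
#' + HNSW (BH), and embeddings + HNSW (the fast configuration).
#'
#' @slot representation \code{"binned"} or \code{"embedding"}.
#' @slot search \code{"brute"} or \code{"hnsw"}.
#' @exportClass MethodVariant
setClass("MethodVariant",
    representation(representation = "character", search = "character")
)

setValidity("MethodVariant", function(object) {
    if (!object@representation %in% c("binned", "embedding"))
        return("representation must be 'binned' or 'embedding'")
    if (!object@search %in% c("brute", "hnsw"))
        return("search must be 'brute' or 'hnsw'")
    TRUE
})

#' Library artifacts: everything needed to match against one library
#'
#' @slot spectra list of [Spectrum-class] objects.
#' @slot binned matrix of weighted binned vectors (rows = spectra), or
#'   \code{NULL} when not materialized.
#' @slot embeddings matrix of spectral embeddings (rows = spectra), or
#'   \code{NULL} when no model was supplied.
#' @slot index [HNSWIndex-class] over the variant's representation, or
#'   \code{NULL} for brute-force variants.
#' @slot idMap spectrum ids in library order.
#' @slot keyMap named character: spectrum id -> molecule canonical key.
#' @slot massMap named numeric: spectrum id -> molecular mass (Da).
#' @slot scheme the [WeightingScheme-class] used for binning.
#' @slot model the [PeakEmbeddingModel-class] used for embeddings, or
#'   \code{NULL}.
#' @slot variant default [MethodVariant-class] for queries.
#' @exportClass LibraryArtifacts
setClass("LibraryArtifacts",
    representation(
        spectra = "list",
        binned = "matrixOrNULL",
        embeddings = "matrixOrNULL",
        index = "HNSWIndexOrNULL",
        idMap = "character",
        keyMap = "character",
        massMap = "numeric",
        scheme = "WeightingScheme",
        model = "PeakEmbeddingModelOrNULL",
        variant = "MethodVariant"
    )
)

setValidity("LibraryArtifacts", function(object) {
    n <- length(object@spectra)
    if (n < 1L) return("library must contain at least one spectrum")
    if (length(object@idMap) != n)
        return("idMap length must equal number of spectra")
    if (!is.null(object@binned) && nrow(object@binned) != n)
        return("binned matrix rows must equal number of spectra")
    if (!is.null(object@embeddings) && nrow(object@embeddings) != n)
        return("embeddings matrix rows must equal number of spectra")
    TRUE
})

#' Recall-at-k evaluation result
#'
#' @slot perK named numeric: recall value in [0,1] for each k.
#' @slot nQueries number of evaluated queries.
#' @slot excluded queries whose true molecule is absent from the library
#'   (counted separately, not folded into recall).
#' @slot variant the [MethodVariant-class] evaluated.
#' @slot massFilterDa mass-filter tolerance in Da (\code{NA} = no filter).
#' @exportClass EvalResult
setClass("EvalResult",
    representation(
        perK = "numeric", nQueries = "integer", excluded = "integer",
        variant = "MethodVariant", massFilterDa = "numeric"
    ),
    prototype(excluded = 0L, massFilterDa = NA_real_)
)

setValidity("EvalResult", function(object) {
    if (any(object@perK < 0 | object@perK > 1))
        return("recall values must lie in [0, 1]")
    ks <- as.integer(names(object@perK))
    if (any(is.na(ks))) return("perK must be named by integer k")
    if (is.unsorted(object@perK[order(ks)]))
        return("recall must be non-decreasing in k")
    TRUE
})

#' Synthetic library generator parameters
#'
#' Controls the generator that emulates an in-silico EI-MS library
#' (integer m/z, sparse peaks, heavy-tailed intensities, base-peak
#' normalized) together with a measured-vs-predicted perturbation model.
#' Molecules draw fragments from a shared pool with class structure, so
#' recurring fragment combinations exist for the embedding to learn; pool
#' fragments carry an alternative m/z ("variant") that perturbation can
#' swap to, emulating systematic predicted-vs-measured peak-position
#' differences.
#'
#' @slot nMolecules library size.
#' @slot mzRange integer (min, max) fragment m/z in Da.
#' @slot peaksPerSpectrum mean peak count (Poisson).
#' @slot intensityTail Pareto shape of the intensity distribution; smaller
#'   values give heavier tails.
#' @slot sharedFragmentPool size of the common fragment vocabulary.
#' @slot nClasses number of molecule classes sharing fragment signatures.
#' @slot noise list with elements \code{jitterSd} (log-normal intensity
#'   jitter), \code{dropoutProb} (peak dropout probability),
#'   \code{spuriousRate} (mean count of added low-intensity peaks) and
#'   \code{swapProb} (probability a pool fragment flips to its alternative
#'   m/z).
#' @slot seed RNG seed.
#' @exportClass SynthParams
setClass("SynthParams",
    representation(
        nMolecules = "integer", mzRange = "integer",
        peaksPerSpectrum = "numeric", intensityTail = "numeric",
        sharedFragmentPool = "integer", nClasses = "integer",
        noise = "list", seed = "integer"
    )
)

setValidity("SynthParams", function(object) {
    if (object@nMolecules < 1L) return("nMolecules must be >= 1")
    if (length(object@mzRange) != 2L || object@mzRange[1L] <= 0L ||
        object@mzRange[2L] > 1000L || object@mzRange[1L] >= object@mzRange[2L])
        return("mzRange must be increasing and within (0, 1000]")
    need <- c("jitterSd", "dropoutProb", "spuriousRate", "swapProb")
    if (!all(need %in% names(object@noise)))
        return(paste("noise must contain", paste(need, collapse = ", ")))
    if (object@noise$dropoutProb < 0 || object@noise$dropoutProb > 1 ||
        object@noise$swapProb < 0 || object@noise$swapProb > 1)
        return("noise probabilities must lie in [0, 1]")
    TRUE
})
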
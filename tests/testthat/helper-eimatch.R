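# Shared helpers: in-code fixtures and independent oracles.

# random integer-m/z spectrum drawn from the caller's RNG stream
randomSpectrum <- function(id, npeaks = 12L, mzMax = 500L) {
    mz <- sort(sample(20:mzMax, npeaks))
    Spectrum(id, mz, runif(npeaks, 0.01, 1), name = paste0("cmpd-", id),
             molMass = max(mz) + sample(0:10, 1L), source = "synthetic")
}

randomSpectra <- function(n, seed = 1L, ...) {
    set.seed(seed)
    lapply(seq_len(n), function(i)
        randomSpectrum(sprintf("S%04d", i), ...))
}

# independent ranking oracle: explicit per-element cosine plus sort,
# sharing no code with bruteForceRank
oracleRank <- function(q, mat, K) {
    sims <- vapply(seq_len(nrow(mat)), function(i) {
        v <- mat[i, ]
        sum(q * v) / sqrt(sum(q^2) * sum(v^2))
    }, numeric(1))
    ids <- rownames(mat)
    o <- order(-sims, ids)[seq_len(K)]
    data.frame(rank = seq_len(K), id = ids[o], similarity = sims[o],
               stringsAsFactors = FALSE)
}

# random unit vectors with ids
unitVectors <- function(n, d, seed = 1L, prefix = "v") {
    set.seed(seed)
    X <- matrix(rnorm(n * d), n)
    X <- X / sqrt(rowSums(X^2))
    rownames(X) <- sprintf("%s%05d", prefix, seq_len(n))
    X
}

# small trained model over a synthetic library, shared across tests
smallBenchmark <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        p <- SynthParams(nMolecules = 300L, seed = 71L)
        lib <- makeLibrary(p)
        model <- trainEmbeddingModel(
            lapply(lib$spectra, spectrumToDocument),
            EmbeddingParams(dim = 32L, epochs = 5L, seed = 71L))
        cache <<- list(p = p, lib = lib, model = model)
        cache
    }
})
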
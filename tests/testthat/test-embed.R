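# Peak-word documents, CBOW training and spectral embeddings.

test_that("a fragment at m/z 89 becomes the word Peak@89", {
    d <- spectrumToDocument(Spectrum("a", 89, 1))
    expect_identical(d@words, "Peak@89")
    expect_equal(d@weights, 1)
})

test_that("near-coincident peaks merge into one word at unit precision", {
    d <- spectrumToDocument(Spectrum("a", c(89.4, 89.2), c(0.6, 0.4)))
    expect_identical(d@words, "Peak@89")
    expect_equal(d@weights, 1)   # merged then normalized to base peak
    d1 <- spectrumToDocument(Spectrum("a", c(89.4, 89.2), c(0.6, 0.4)),
                             precision = 1L)
    expect_identical(d1@words, c("Peak@89.2", "Peak@89.4"))
})

test_that("document weights are monotone in intensity for alpha > 0", {
    set.seed(3)
    s <- normalizeSpectrum(randomSpectrum("a", npeaks = 10L))
    d <- spectrumToDocument(s, alpha = 0.5)
    expect_length(d@words, 10L)
    expect_identical(order(d@weights), order(intensity(s)))
})

test_that("training covers frequent words and is deterministic by seed", {
    lib <- smallBenchmark()$lib
    corpus <- lapply(lib$spectra[1:100], spectrumToDocument)
    params <- EmbeddingParams(dim = 16L, epochs = 5L, seed = 42L)
    m1 <- trainEmbeddingModel(corpus, params)
    allWords <- unique(unlist(lapply(corpus, function(d) d@words)))
    expect_setequal(rownames(m1@vectors), allWords)
    expect_equal(ncol(m1@vectors), 16L)
    m2 <- trainEmbeddingModel(corpus, params)
    expect_identical(m1@vectors, m2@vectors)
    m3 <- trainEmbeddingModel(corpus,
                              EmbeddingParams(dim = 16L, epochs = 5L,
                                              seed = 43L))
    expect_false(identical(m1@vectors, m3@vectors))
})

test_that("always-co-occurring words end up closer than never-co-occurring
           words", {
    # planted corpus: documents draw either vocabulary block A or block B;
    # words within a block always co-occur, across blocks never
    set.seed(5)
    A <- sprintf("Peak@%d", 100:109)
    B <- sprintf("Peak@%d", 300:309)
    docs <- lapply(1:200, function(i) {
        w <- if (i %% 2) sample(A, 6) else sample(B, 6)
        new("PeakDocument", words = w, weights = rep(1, 6))
    })
    m <- trainEmbeddingModel(docs, EmbeddingParams(dim = 16L, epochs = 20L,
                                                   seed = 7L))
    v <- m@vectors / sqrt(rowSums(m@vectors^2))
    within <- mean((v[A, ] %*% t(v[A, ]))[upper.tri(diag(10))])
    across <- mean(v[A, ] %*% t(v[B, ]))
    expect_gt(within, across)
})

test_that("skip-gram architecture also trains deterministically", {
    lib <- smallBenchmark()$lib
    corpus <- lapply(lib$spectra[1:50], spectrumToDocument)
    params <- EmbeddingParams(dim = 8L, epochs = 3L, seed = 2L,
                              architecture = "skipgram")
    m1 <- trainEmbeddingModel(corpus, params)
    m2 <- trainEmbeddingModel(corpus, params)
    expect_identical(m1@vectors, m2@vectors)
})

test_that("a single-peak spectrum embeds to that word's normalized vector", {
    bm <- smallBenchmark()
    w <- rownames(bm$model@vectors)[1L]
    mzv <- as.numeric(sub("Peak@", "", w))
    e <- embedSpectrum(Spectrum("one", mzv, 1), bm$model)
    ref <- bm$model@vectors[w, ]
    expect_equal(e@vector, ref / sqrt(sum(ref^2)), tolerance = 1e-12)
    expect_equal(sqrt(sum(e@vector^2)), 1, tolerance = 1e-12)
})

test_that("embedding is deterministic, permutation- and scale-invariant", {
    bm <- smallBenchmark()
    s <- bm$lib$spectra[[5L]]
    e1 <- embedSpectrum(s, bm$model)
    perm <- sample(nrow(peaks(s)))
    sPerm <- Spectrum("p", mz(s)[perm], intensity(s)[perm])
    sScaled <- Spectrum("c", mz(s), 37 * intensity(s))
    expect_equal(embedSpectrum(sPerm, bm$model)@vector, e1@vector,
                 tolerance = 1e-12)
    expect_equal(embedSpectrum(sScaled, bm$model)@vector, e1@vector,
                 tolerance = 1e-12)
})

test_that("the raw embedding is linear in the peak contributions", {
    bm <- smallBenchmark()
    words <- rownames(bm$model@vectors)
    mzv <- as.numeric(sub("Peak@", "", words[1:6]))
    s1 <- Spectrum("a", mzv[1:3], c(1, 0.5, 0.25))
    s2 <- Spectrum("b", mzv[4:6], c(1, 0.5, 0.25))
    merged <- Spectrum("m", mzv, c(1, 0.5, 0.25, 1, 0.5, 0.25))
    e1 <- embedSpectrum(s1, bm$model, normalize = FALSE)@vector
    e2 <- embedSpectrum(s2, bm$model, normalize = FALSE)@vector
    em <- embedSpectrum(merged, bm$model, normalize = FALSE)@vector
    expect_equal(em, e1 + e2, tolerance = 1e-10)
})

test_that("out-of-vocabulary peaks are skipped with a counter; all-OOV is
           an error naming the spectrum", {
    bm <- smallBenchmark()
    words <- rownames(bm$model@vectors)
    mzv <- as.numeric(sub("Peak@", "", words[1:4]))
    inVocab <- Spectrum("iv", mzv, c(1, 0.6, 0.3, 0.1))
    oovMz <- setdiff(600:980, as.numeric(sub("Peak@", "", words)))[1:2]
    withOov <- Spectrum("ov", c(mzv, oovMz), c(1, 0.6, 0.3, 0.1, 0.2, 0.1))
    eo <- embedSpectrum(withOov, bm$model)
    expect_equal(eo@oov, 2L)
    expect_equal(eo@vector, embedSpectrum(inVocab, bm$model)@vector,
                 tolerance = 1e-12)
    expect_error(embedSpectrum(Spectrum("gone", oovMz, c(1, 0.5)),
                               bm$model), "gone")
})

test_that("a saved model reloads with identical vectors and parameters", {
    bm <- smallBenchmark()
    f <- withr::local_tempfile(fileext = ".json")
    saveEmbeddingModel(bm$model, f)
    back <- loadEmbeddingModel(f)
    expect_identical(back@vectors, bm$model@vectors)
    expect_equal(back@params@dim, bm$model@params@dim)
    expect_identical(back@corpusFingerprint, bm$model@corpusFingerprint)
    bad <- withr::local_tempfile(fileext = ".json")
    writeLines('{"format": "other"}', bad)
    expect_error(loadEmbeddingModel(bad), "version")
})
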
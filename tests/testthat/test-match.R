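# Pipeline artifacts, querying, mass filter, recall and expansion.

test_that("artifact bookkeeping matches the variant contract", {
    bm <- smallBenchmark()
    spectra <- bm$lib$spectra[1:100]
    hp <- HNSWParams(M = 8L, efConstruction = 40L, ef = 30L, seed = 2L)
    artF <- buildArtifacts(spectra, model = bm$model, hnswParams = hp,
                           keyMap = bm$lib$truth[1:100])
    expect_equal(hnswSize(artF@index), 100L)
    expect_equal(nrow(artF@embeddings), 100L)
    artW <- buildArtifacts(spectra, scheme = WeightingScheme(),
                           variant = methodVariant("wcs"))
    expect_null(artW@index)
    expect_null(artW@embeddings)
    expect_error(buildArtifacts(spectra, variant = methodVariant("ec")),
                 "model")
})

test_that("artifacts rebuilt from the same inputs and seeds are
           bit-identical", {
    bm <- smallBenchmark()
    spectra <- bm$lib$spectra[1:60]
    hp <- HNSWParams(M = 6L, efConstruction = 30L, ef = 20L, seed = 5L)
    a1 <- buildArtifacts(spectra, model = bm$model, hnswParams = hp)
    a2 <- buildArtifacts(spectra, model = bm$model, hnswParams = hp)
    expect_identical(a1@binned, a2@binned)
    expect_identical(a1@embeddings, a2@embeddings)
    expect_identical(hnswGraph(a1@index), hnswGraph(a2@index))
})

test_that("querying a library member returns it at rank 1 with cosine 1", {
    bm <- smallBenchmark()
    spectra <- bm$lib$spectra[1:80]
    for (v in c("wcs", "ec")) {
        art <- buildArtifacts(spectra, model = bm$model,
                              variant = methodVariant(v))
        cand <- searchLibrary(spectra[[17L]], art, K = 5L)
        expect_identical(cand$id[1L], spectrumId(spectra[[17L]]))
        expect_equal(cand$similarity[1L], 1, tolerance = 1e-9)
    }
})

test_that("K = library size with brute search is a total ranking", {
    bm <- smallBenchmark()
    spectra <- bm$lib$spectra[1:40]
    art <- buildArtifacts(spectra, variant = methodVariant("wcs"))
    cand <- searchLibrary(spectra[[1L]], art, K = 40L)
    expect_setequal(cand$id, vapply(spectra, spectrumId, character(1)))
})

test_that("an hnsw query against a mismatched representation is a clear
           error", {
    bm <- smallBenchmark()
    art <- buildArtifacts(bm$lib$spectra[1:30], model = bm$model,
                          hnswParams = HNSWParams(M = 4L,
                                                  efConstruction = 10L,
                                                  ef = 10L))
    expect_error(searchLibrary(bm$lib$spectra[[1L]], art, K = 5L,
                               variant = methodVariant("bh")),
                 "representation")
})

test_that("the mass filter keeps a 4.9 Da candidate and drops a 5.1 Da one
           at 5 Da tolerance", {
    cand <- data.frame(rank = 1:3, id = c("a", "b", "c"),
                       similarity = c(0.9, 0.8, 0.7),
                       molMass = c(154.9, 155.1, NA))
    out <- massFilter(cand, queryMass = 150, tol = 5)
    expect_identical(out$id, "a")
    expect_equal(out$rank, 1L)
    expect_equal(attr(out, "missingMass"), 1L)
    # infinite tolerance keeps every mass-bearing candidate in order
    all3 <- massFilter(cand, 150, tol = Inf)
    expect_identical(all3$id, c("a", "b"))
})

test_that("recall@k thresholds behave at the rank boundary", {
    mk <- function(hit) {
        data.frame(rank = 1:10, id = sprintf("L%02d", 1:10),
                   key = replace(sprintf("K%02d", 1:10), hit, "TRUE_KEY"))
    }
    res <- list(q1 = mk(1L))
    ev1 <- recallAtK(res, c(q1 = "TRUE_KEY"), ks = c(1L, 10L))
    expect_equal(unname(ev1@perK), c(1, 1))
    res7 <- list(q1 = mk(7L), q2 = mk(7L))
    ev7 <- recallAtK(res7, c(q1 = "TRUE_KEY", q2 = "TRUE_KEY"),
                     ks = c(1L, 10L))
    expect_equal(unname(ev7@perK), c(0, 1))
    expect_false(is.unsorted(ev7@perK))
})

test_that("random rankings recover the closed-form expectation k/N", {
    set.seed(91)
    N <- 100L
    keys <- sprintf("K%03d", 1:N)
    res <- lapply(1:1000, function(i) {
        data.frame(rank = 1:10, id = sprintf("L%02d", 1:10),
                   key = sample(keys, 10L))
    })
    names(res) <- sprintf("q%04d", 1:1000)
    truth <- setNames(sample(keys, 1000L, replace = TRUE), names(res))
    ev <- recallAtK(res, truth, ks = 10L)
    p <- 10 / N
    se <- sqrt(p * (1 - p) / 1000)
    expect_lt(abs(ev@perK[["10"]] - p), 4 * se)
})

test_that("queries whose truth is outside the library are excluded with a
           warning", {
    res <- list(q1 = data.frame(rank = 1L, id = "a", key = "KA"),
                q2 = data.frame(rank = 1L, id = "a", key = "KA"))
    truth <- c(q1 = "KA", q2 = "MISSING")
    expect_warning(
        ev <- recallAtK(res, truth, ks = 1L, libraryKeys = "KA"),
        "excluded")
    expect_equal(ev@nQueries, 1L)
    expect_equal(ev@excluded, 1L)
    expect_equal(unname(ev@perK), 1)
})

test_that("mass filtering with exact true masses never lowers recall", {
    bm <- smallBenchmark()
    hp <- HNSWParams(M = 8L, efConstruction = 40L, ef = 40L, seed = 2L)
    art <- buildArtifacts(bm$lib$spectra, model = bm$model,
                          hnswParams = hp, keyMap = bm$lib$truth)
    q <- makeQueries(bm$lib, bm$p, which = 1:100)
    ks <- c(1L, 3L, 10L)
    before <- evaluateMatching(q$spectra, art, q$truth, ks = ks, K = 50L)
    after <- evaluateMatching(q$spectra, art, q$truth, ks = ks, K = 50L,
                              massFilterDa = 5)
    expect_true(all(after@perK >= before@perK - 1e-12))
})

test_that("expansion is incremental, preserves old entries and rejects
           duplicate ids", {
    bm <- smallBenchmark()
    hp <- HNSWParams(M = 8L, efConstruction = 40L, ef = 30L, seed = 2L)
    art <- buildArtifacts(bm$lib$spectra[1:200], model = bm$model,
                          hnswParams = hp,
                          keyMap = bm$lib$truth[1:200])
    expect_identical(expandLibrary(art, list()), art)
    ptrBefore <- art@index@ptr
    extra <- bm$lib$spectra[201:210]
    art2 <- expandLibrary(art, extra, keyMap = bm$lib$truth[201:210])
    expect_equal(length(art2@spectra), 210L)
    expect_equal(hnswSize(art2@index), 210L)
    expect_identical(art2@index@ptr, ptrBefore)   # no rebuild
    expect_identical(art2@idMap[1:200], art@idMap[1:200])
    cand <- searchLibrary(bm$lib$spectra[[3L]], art2, K = 5L)
    expect_identical(cand$id[1L], spectrumId(bm$lib$spectra[[3L]]))
    expect_error(expandLibrary(art2, extra), "duplicate")
})

test_that("recall is non-decreasing in k for every variant", {
    bm <- smallBenchmark()
    hp <- HNSWParams(M = 8L, efConstruction = 40L, ef = 40L, seed = 2L)
    artE <- buildArtifacts(bm$lib$spectra, model = bm$model,
                           hnswParams = hp, keyMap = bm$lib$truth)
    artB <- buildArtifacts(bm$lib$spectra, model = bm$model,
                           hnswParams = hp, keyMap = bm$lib$truth,
                           variant = methodVariant("bh"))
    q <- makeQueries(bm$lib, bm$p, which = 1:60)
    for (v in c("wcs", "ec", "bh", "fastei")) {
        art <- if (v == "bh") artB else artE
        ev <- evaluateMatching(q$spectra, art, q$truth,
                               ks = c(1L, 2L, 5L, 10L, 20L), K = 50L,
                               variant = methodVariant(v))
        expect_false(is.unsorted(ev@perK))
    }
})
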
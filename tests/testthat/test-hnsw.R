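# The from-scratch HNSW index: level law, structure, search quality,
# persistence.

test_that("level assignment follows the exponential law", {
    # degenerate multiplier: always level 0
    expect_true(all(assignLevel(1000L, mL = 1e-12, seed = 1L) == 0))
    # reproducible for a fixed seed
    expect_identical(assignLevel(50L, 0.36, seed = 9L),
                     assignLevel(50L, 0.36, seed = 9L))
    # survival function P(l >= k) = exp(-k / mL)
    mL <- 1 / log(16)
    lv <- assignLevel(100000L, mL, seed = 4L)
    for (k in 1:3) {
        p <- exp(-k / mL)
        se <- sqrt(p * (1 - p) / 100000)
        expect_lt(abs(mean(lv >= k) - p), 4 * se + 1e-4)
    }
    # the underlying exponential draw has mean mL (same RNG stream)
    raw <- assignLevel(100000L, mL, seed = 4L, raw = TRUE)
    expect_equal(floor(raw), lv)
    expect_lt(abs(mean(raw) - mL), 3 * sd(raw) / sqrt(100000))
})

test_that("the first insertion becomes the entry point; duplicates and
           dimension mismatches are errors", {
    idx <- hnswIndex(4L, HNSWParams(M = 4L, efConstruction = 8L, ef = 4L))
    hnswInsert(idx, matrix(c(1, 0, 0, 0), 1L), ids = "a")
    g <- hnswGraph(idx)
    expect_identical(g$ids[g$entry], "a")
    expect_equal(hnswSize(idx), 1L)
    expect_error(hnswInsert(idx, matrix(0.5, 1L, 4L), ids = "a"),
                 "duplicate")
    expect_error(hnswInsert(idx, matrix(0.5, 1L, 5L), ids = "b"),
                 "dimension")
})

test_that("structural invariants hold after every insertion batch", {
    X <- unitVectors(100, 8, seed = 21)
    idx <- hnswIndex(8L, HNSWParams(M = 4L, efConstruction = 20L, ef = 10L,
                                    seed = 3L))
    for (batch in split(1:100, rep(1:4, each = 25))) {
        hnswInsert(idx, X[batch, , drop = FALSE])
        expect_true(all(hnswAudit(idx)))
    }
    expect_equal(hnswSize(idx), 100L)
})

test_that("an exact duplicate vector is retrieved with its twin at
           distance 0", {
    X <- unitVectors(50, 8, seed = 5)
    X <- rbind(X, dup = X[10L, ])
    rownames(X)[51L] <- "dup"
    idx <- hnswIndex(8L, HNSWParams(M = 8L, efConstruction = 30L, ef = 20L))
    hnswInsert(idx, X)
    res <- hnswSearch(idx, X[10L, ], K = 2L, ef = 20L)
    expect_setequal(res$id, c(rownames(X)[10L], "dup"))
    expect_equal(res$distance, c(0, 0), tolerance = 1e-12)
})

test_that("with ef = index size on a small index, search is exact", {
    X <- unitVectors(200, 12, seed = 31)
    idx <- hnswIndex(12L, HNSWParams(M = 8L, efConstruction = 200L,
                                     ef = 200L, seed = 2L))
    hnswInsert(idx, X)
    set.seed(32)
    agree <- vapply(1:30, function(i) {
        q <- rnorm(12)
        q <- q / sqrt(sum(q^2))
        got <- hnswSearch(idx, q, K = 10L, ef = 200L)$id
        want <- bruteForceRank(q, X, K = 10L)$id
        mean(got == want)
    }, numeric(1))
    expect_gte(mean(agree == 1), 0.99)
})

test_that("self-retrieval: a stored vector is its own nearest neighbour", {
    X <- unitVectors(300, 16, seed = 41)
    idx <- hnswIndex(16L, HNSWParams(M = 8L, efConstruction = 60L,
                                     ef = 50L, seed = 2L))
    hnswInsert(idx, X)
    for (i in c(1L, 150L, 300L)) {
        res <- hnswSearch(idx, X[i, ], K = 1L, ef = 50L)
        expect_identical(res$id, rownames(X)[i])
        expect_equal(res$distance, 0, tolerance = 1e-12)
    }
})

test_that("K = 1 on a two-element index returns the closer element;
           contract errors fire", {
    idx <- hnswIndex(2L, HNSWParams(M = 2L, efConstruction = 4L, ef = 4L))
    hnswInsert(idx, rbind(a = c(1, 0), b = c(0, 1)))
    expect_identical(hnswSearch(idx, c(0.9, 0.1), K = 1L, ef = 4L)$id, "a")
    expect_error(hnswSearch(idx, c(1, 0), K = 5L, ef = 2L), "exceed")
    empty <- hnswIndex(2L, HNSWParams(M = 2L, efConstruction = 4L, ef = 4L))
    expect_error(hnswSearch(empty, c(1, 0), K = 1L, ef = 2L), "empty")
})

test_that("recall is monotone in ef and reaches 1.0 at full width", {
    X <- unitVectors(500, 24, seed = 51)
    idx <- hnswIndex(24L, HNSWParams(M = 8L, efConstruction = 100L,
                                     ef = 50L, seed = 6L))
    hnswInsert(idx, X)
    set.seed(52)
    Q <- matrix(rnorm(40 * 24), 40)
    Q <- Q / sqrt(rowSums(Q^2))
    recallAt <- function(ef) {
        mean(vapply(1:40, function(i) {
            got <- hnswSearch(idx, Q[i, ], K = 10L, ef = ef)$id
            length(intersect(got, bruteForceRank(Q[i, ], X, 10L)$id)) / 10
        }, numeric(1)))
    }
    r <- vapply(c(10L, 20L, 80L, 500L), recallAt, numeric(1))
    expect_true(all(diff(r) >= -1e-9))
    expect_equal(r[4L], 1.0)
})

test_that("save -> load reproduces 50 searches bit-identically", {
    X <- unitVectors(150, 8, seed = 61)
    idx <- hnswIndex(8L, HNSWParams(M = 6L, efConstruction = 40L, ef = 20L,
                                    seed = 4L))
    hnswInsert(idx, X)
    f <- withr::local_tempfile(fileext = ".json")
    hnswSave(idx, f)
    back <- hnswLoad(f)
    expect_equal(hnswSize(back), 150L)
    set.seed(62)
    for (i in 1:50) {
        q <- rnorm(8)
        expect_identical(hnswSearch(idx, q, K = 5L, ef = 20L),
                         hnswSearch(back, q, K = 5L, ef = 20L))
    }
    # the restored graph continues inserting identically to the original
    Y <- unitVectors(20, 8, seed = 63, prefix = "y")
    hnswInsert(idx, Y)
    hnswInsert(back, Y)
    expect_identical(hnswGraph(idx), hnswGraph(back))
})

test_that("an empty index saves and loads; corrupted files error out", {
    idx <- hnswIndex(4L, HNSWParams(M = 2L, efConstruction = 4L, ef = 2L))
    f <- withr::local_tempfile(fileext = ".json")
    hnswSave(idx, f)
    expect_equal(hnswSize(hnswLoad(f)), 0L)
    bad <- withr::local_tempfile(fileext = ".json")
    writeLines("{\"format\": \"bogus\"}", bad)
    expect_error(hnswLoad(bad), "version")
    garbage <- withr::local_tempfile(fileext = ".json")
    writeLines("not json at all {{{", garbage)
    expect_error(hnswLoad(garbage), "")
})

test_that("construction is deterministic for a fixed seed and insertion
           order", {
    X <- unitVectors(120, 8, seed = 71)
    build <- function() {
        idx <- hnswIndex(8L, HNSWParams(M = 6L, efConstruction = 30L,
                                        ef = 20L, seed = 8L))
        hnswInsert(idx, X)
        hnswGraph(idx)
    }
    expect_identical(build(), build())
})
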
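# Molecule descriptors, the filtering rules and deduplication.

# hand-built descriptor rows let the rule logic be tested independently
# of the structure toolkit
fakeRecord <- function(key = "K", mass = 100, elements = c("C", "H"),
                       ionic = FALSE, logp = 1, dataset = "t") {
    out <- data.frame(smiles = key, canonical_key = key, mol_mass = mass,
                      is_ionic = ionic, logp = logp, dataset = dataset,
                      stringsAsFactors = FALSE)
    out$elements <- list(elements)
    out
}

test_that("toolkit descriptors for ethanol match known values", {
    d <- computeDescriptors("CCO")
    expect_setequal(d$elements[[1L]], c("C", "H", "O"))
    expect_equal(d$mol_mass, 46.07, tolerance = 1e-3)
    expect_false(d$is_ionic)
    expect_equal(nchar(d$canonical_key), 27L)
    f <- applyFilters(d)
    expect_true(f$passed)
    expect_length(f$failed_rules[[1L]], 0L)
})

test_that("an explicit salt is flagged ionic and fails R3", {
    d <- computeDescriptors("[Na+].[Cl-]")
    expect_true(d$is_ionic)
    f <- applyFilters(d)
    expect_true("R3" %in% f$failed_rules[[1L]])
})

test_that("bromobenzene's elements stay within the 11-element whitelist", {
    d <- computeDescriptors("c1ccccc1Br")
    expect_setequal(d$elements[[1L]], c("C", "H", "Br"))
    expect_true(all(d$elements[[1L]] %in% elementWhitelist))
    expect_true(applyFilters(d)$passed)
})

test_that("an unparseable SMILES raises an error naming the string", {
    expect_error(computeDescriptors("not_a_smiles(("), "not_a_smiles")
})

test_that("each filtering rule trips on its own threshold", {
    cases <- list(
        list(rec = fakeRecord(mass = 1200), rule = "R1"),
        list(rec = fakeRecord(mass = 1000), rule = "R1"),  # bound exclusive
        list(rec = fakeRecord(elements = c("C", "H", "Se")), rule = "R2"),
        list(rec = fakeRecord(ionic = TRUE), rule = "R3"),
        list(rec = fakeRecord(logp = 25), rule = "R4"),
        list(rec = fakeRecord(logp = -13), rule = "R4")
    )
    for (cs in cases) {
        f <- applyFilters(cs$rec)
        expect_false(f$passed)
        expect_true(cs$rule %in% f$failed_rules[[1L]])
    }
    # inclusive logP bounds and just-under-mass pass
    ok <- applyFilters(rbind(fakeRecord(logp = 24), fakeRecord(logp = -12),
                             fakeRecord(mass = 999.99)))
    expect_true(all(ok$passed))
})

test_that("passing is exactly the conjunction of R1-R4", {
    set.seed(4)
    for (i in 1:30) {
        rec <- fakeRecord(
            mass = sample(c(500, 1500), 1L),
            elements = if (runif(1) < 0.5) c("C", "H") else c("C", "H", "U"),
            ionic = runif(1) < 0.5,
            logp = sample(c(0, 30), 1L)
        )
        f <- applyFilters(rec)
        expect_identical(f$passed, length(f$failed_rules[[1L]]) == 0L)
    }
})

test_that("representation variants of one molecule share a canonical key
           and deduplicate", {
    d <- computeDescriptors(c("CCO", "OCC"))
    expect_identical(d$canonical_key[1L], d$canonical_key[2L])
    expect_equal(nrow(dedupWithin(d)), 1L)
    expect_identical(dedupWithin(d)$smiles, "CCO")  # first kept, order stable
})

test_that("dedupWithin keeps all-distinct lists unchanged and counts
           distinct keys with planted duplicates", {
    set.seed(8)
    keys <- sprintf("K%02d", 1:20)
    distinct <- do.call(rbind, lapply(keys, fakeRecord))
    expect_identical(dedupWithin(distinct), distinct)
    planted <- distinct[sample(1:20, 60, replace = TRUE), ]
    expect_equal(nrow(dedupWithin(planted)),
                 length(unique(planted$canonical_key)))
})

test_that("dedupAcross removes earlier-dataset molecules from later ones", {
    nist <- rbind(fakeRecord("A"), fakeRecord("B"))
    chembl <- rbind(fakeRecord("B"), fakeRecord("C"))
    out <- dedupAcross(list(nist = nist, chembl = chembl))
    expect_identical(out$nist$canonical_key, c("A", "B"))
    expect_identical(out$chembl$canonical_key, "C")
    # disjoint datasets pass through unchanged
    d1 <- rbind(fakeRecord("X"), fakeRecord("Y"))
    d2 <- rbind(fakeRecord("Z"))
    out2 <- dedupAcross(list(d1, d2))
    expect_identical(out2[[1L]], d1)
    expect_identical(out2[[2L]], d2)
})

test_that("the union after dedupAcross has exactly the distinct keys", {
    set.seed(15)
    pool <- sprintf("M%03d", 1:60)
    sets <- lapply(1:3, function(i) {
        ks <- unique(sample(pool, 40, replace = TRUE))
        do.call(rbind, lapply(ks, fakeRecord))
    })
    out <- dedupAcross(sets)
    keys <- unlist(lapply(out, `[[`, "canonical_key"))
    expect_identical(anyDuplicated(keys), 0L)
    expect_setequal(keys, unique(unlist(lapply(sets, `[[`,
                                               "canonical_key"))))
    expect_equal(length(keys),
                 length(unique(unlist(lapply(sets, `[[`,
                                             "canonical_key")))))
})

test_that("librarySizes composes disjoint component sizes by summation", {
    comp <- c(a = 10, b = 5, c = 2)
    out <- librarySizes(comp, list(ab = c("a", "b"),
                                   all = c("a", "b", "c")))
    expect_equal(out, c(ab = 15, all = 17))
    expect_error(librarySizes(comp, list(x = "nope")), "unknown components")
})

test_that("SMILES lists and filter reports read and write", {
    f <- withr::local_tempfile(fileext = ".smi")
    writeLines(c("CCO\tethanol", "c1ccccc1"), f)
    sl <- readSmilesList(f)
    expect_equal(sl$smiles, c("CCO", "c1ccccc1"))
    expect_equal(sl$id[1L], "ethanol")
    rep <- applyFilters(computeDescriptors(sl$smiles))
    out <- withr::local_tempfile(fileext = ".tsv")
    writeFilterReport(rep, out)
    back <- read.table(out, sep = "\t", header = TRUE)
    expect_equal(nrow(back), 2L)
    expect_true(all(back$passed))
})
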
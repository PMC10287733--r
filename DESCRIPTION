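Package: eimatch
Title: Spectral Embedding and Graph-Based Approximate Search for
    Electron-Ionization Mass Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compound identification for electron-ionization mass
    spectrometry (EI-MS) by spectral library search. Spectra are
    represented either as weighted m/z-binned vectors compared with the
    weighted cosine similarity, or as low-dimensional embeddings obtained
    by training a continuous-bag-of-words model on "peak words" and
    summing peak vectors. A hierarchical navigable small-world (HNSW)
    proximity graph, implemented from scratch, provides approximate
    nearest-neighbour retrieval that scales to large in-silico libraries.
    Includes NIST MSP reading and writing, the molecule filtering and
    deduplication rules used to assemble in-silico libraries from
    structure databases, a recall-at-k evaluation harness with an optional
    molecular-mass filter, incremental library expansion, and a synthetic
    spectrum generator for end-to-end benchmarking without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
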
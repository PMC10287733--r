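# eimatch

Compound identification for electron-ionization mass spectrometry (EI-MS)
by spectral library search, built for the regime where the reference
library is a large *in-silico* collection of predicted spectra rather
than a small measured one.

**Who it is for.** GC-MS practitioners and method developers who need to
match measured 70 eV EI spectra against libraries from thousands to
millions of entries, and who want both the classical baseline and the
fast, embedding-based alternative in one auditable implementation.

## The method

A spectrum can be represented two ways:

* **Weighted binned vector** — an *m*-dimensional vector over unit m/z
  bins whose entry is `Σ Iᵃ·(m/z)ᵇ` over the bin's peaks (defaults
  *a* = 0.5, *b* = 2). Two spectra are compared with the **weighted
  cosine similarity (WCS)**, `⟨x,y⟩ / (‖x‖·‖y‖)`.
* **Spectral embedding** — each integer m/z becomes a peak word
  (`Peak@89` for a fragment at m/z 89); a continuous-bag-of-words model
  with negative sampling is trained on the library corpus (defaults:
  d = 500, window 1000, negative = 5, lr 0.025 with 0.00025/epoch decay,
  60 epochs), and a spectrum embeds as the intensity-weighted sum of its
  peak-word vectors, L2-normalized.

Retrieval is either **exact** (brute-force cosine ranking, also the
oracle in the test suite) or **approximate** through a from-scratch
**hierarchical navigable small-world (HNSW)** graph: layers drawn from an
exponential level law `l = ⌊−ln(u)·m_L⌋`, greedy search-layer traversal
with a dynamic candidate list, bidirectional M-linking with heuristic
neighbour selection (defaults M = 64, efConstruction = 600, ef = 300),
incremental insertion, and plain-text persistence. The four
representation × search combinations give the standard ablation: WCS,
EC (embeddings + exact), BH (bins + HNSW) and the fast configuration
(embeddings + HNSW). A post-retrieval molecular-mass filter (±5 Da,
inclusive) and a recall@k harness complete the pipeline, and a synthetic
generator emulates a predicted library plus measured queries so
everything runs without licensed data.

Library preparation implements the standard filters for EI-MS library
membership — mass < 1000 Da, the 11-element whitelist
(H, C, O, N, P, S, Cl, F, Br, I, Si), non-ionic, logP in [−12, 24],
within- and cross-dataset deduplication on InChIKeys — on top of Open
Babel descriptors.

## Worked example

Simulate a 2000-molecule in-silico library with measured-style
(perturbed) queries, train embeddings, build the index, and compare the
classical baseline with the embedding + HNSW configuration:

```r
library(eimatch)

p   <- SynthParams()                     # 2000 molecules, calibrated noise
lib <- makeLibrary(p)
model <- trainEmbeddingModel(lapply(lib$spectra, spectrumToDocument),
                             EmbeddingParams(dim = 64, epochs = 10, seed = 1))
art <- buildArtifacts(lib$spectra, model = model,
                      hnswParams = HNSWParams(M = 16, efConstruction = 200,
                                              ef = 100, seed = 1),
                      keyMap = lib$truth)
art
#> LibraryArtifacts: 2000 spectra (fastei)
#>   binned: 1000 bins; embeddings: 64 dims; index: 2000 vectors

q <- makeQueries(lib, p, which = 1:300)  # perturbed "measured" queries
searchLibrary(q$spectra[[1]], art, K = 3)
#>   rank       id   distance similarity      key molMass
#> 1    1 LIB00001 0.04785155  0.9760742 MOL00001     500
#> 2    2 LIB00010 0.14514310  0.9274284 MOL00010     489
#> 3    3 LIB00795 0.15302812  0.9234859 MOL00795     464
```

The first query is a noisy copy of library molecule `MOL00001`; it is
retrieved at rank 1 with cosine similarity 0.976 (distance is squared
Euclidean between the unit-norm embeddings, `2 − 2·cos`). Evaluating
recall over the 300 queries:

```r
evaluateMatching(q$spectra, art, q$truth, ks = c(1, 10), K = 100,
                 variant = methodVariant("wcs"))
#> EvalResult (wcs), 300 queries
#>   recall@1 = 0.7867
#>   recall@10 = 0.9000

evaluateMatching(q$spectra, art, q$truth, ks = c(1, 10), K = 100)
#> EvalResult (fastei), 300 queries
#>   recall@1 = 0.7600
#>   recall@10 = 0.9300

evaluateMatching(q$spectra, art, q$truth, ks = c(1, 10), K = 100,
                 massFilterDa = 5)
#> EvalResult (fastei), 300 queries, mass filter 5 Da
#>   recall@1 = 0.8433
#>   recall@10 = 0.9733
```

Under the generator's perturbation model — whose dominant channel is
systematic peak-position shifts, the gap embeddings are designed to
absorb — the embedding configuration recovers 93% of true molecules in
the top 10 versus 90% for binned WCS, and the 5 Da mass filter lifts
recall@1 from 0.76 to 0.84 by discarding high-similarity candidates with
the wrong molecular mass. See `vignette("eimatch-methods")` for the
model, parameter and calibration details.

A command-line front end wraps the same functions:

```sh
Rscript inst/exec/eimatch simulate --n 2000 --seed 7 \
    --out library.msp --queries queries.msp --truth truth.tsv
Rscript inst/exec/eimatch train --library library.msp --out model.json \
    --dim 64 --epochs 10
Rscript inst/exec/eimatch eval --library library.msp \
    --spectra queries.msp --truth truth.tsv --model model.json --ks 1,10
```

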
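---
title: "Methods: spectral embedding and graph-based search for EI-MS library matching"
author: "eimatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral embedding and graph-based search for EI-MS library matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eimatch)
```

## The problem

Compound identification in GC-MS rests on matching a measured 70 eV
electron-ionization (EI) spectrum against a reference library. Two things
limit this in practice: measured libraries cover only a small fraction of
known chemical space, and exhaustive similarity scans over a library with
millions of in-silico predicted spectra are slow. `eimatch` implements the
two-sided answer: represent spectra either as classical weighted m/z bins
(scored with the weighted cosine similarity, WCS) or as low-dimensional
embeddings learned from fragment co-occurrence, and retrieve candidates
either exactly (brute force) or approximately through a hierarchical
navigable small-world (HNSW) proximity graph. The four combinations form
an ablation square — WCS (bins + brute), EC (embeddings + brute), BH
(bins + HNSW) and the fast configuration (embeddings + HNSW) — in which
the embedding axis governs accuracy and the index axis governs speed.

## Spectrum representations

**Binned vectors.** A spectrum is an m-dimensional vector over half-open
bins $[kw, (k+1)w)$, 0-based, with a peak exactly at the upper bound
`maxMz` assigned to the last bin (so the stated domain $(0, \mathrm{maxMz}]$
loses no peak). Entry $k$ holds $\sum I_i^a\, m_i^b$ over its peaks. The
defaults $a = 0.5$, $b = 2$, $w = 1$ Da, `maxMz` = 1000 Da follow the
Stein-and-Scott family of weighted dot products used throughout EI library
search; both exponents are configurable because published variants differ,
and every baseline in this package uses one shared scheme so comparisons
isolate representation and search, not weighting. The similarity is the
cosine between two such vectors, which for non-negative entries lies in
$[0, 1]$ and is invariant to joint scaling — hence all intensities are
base-peak normalized to $[0, 1]$ at ingest and the 0–999 NIST convention
is converted on the way in.

**Peak-word embeddings.** Each distinct integer m/z becomes a token
(`Peak@89` for a fragment at m/z 89); a spectrum is a document of such
words. A continuous-bag-of-words (CBOW) model with negative sampling is
trained on the library corpus; skip-gram is available but CBOW is the
default, as it behaves better on these short, orderless documents. The
production hyperparameters are dimension 500, window 1000, 5 negative
samples, initial learning rate 0.025 decaying 0.00025 per epoch, 60
epochs. Two of these deserve comment:

* *Window 1000.* Peak documents have tens of words, so the window always
  spans the whole document: an individual EI fragment carries little
  information, and the deliberate effect is that every peak is context
  for every other peak.
* *Epochs.* The benchmark configuration used by this package's tests is
  dimension 64 and 10 epochs on a 2000-spectrum corpus; these sizes keep
  the full suite within minutes on one core while leaving the qualitative
  behaviour (embeddings beating bins under position noise) intact.

A spectrum embeds as $\sum_i w_i\, v(\mathrm{word}_i)$ with
$w_i = (I_i / I_{\max})^{\alpha}$, $\alpha = 0.5$ by default. Plain
unweighted summation is a configuration away ($\alpha = 0$); the
intensity-weighted reading was chosen because it matches how spectral
embeddings are formed in the Spec2Vec lineage and keeps strong fragments
dominant. Embeddings are L2-normalized, so squared Euclidean distance and
cosine order candidates identically — this is what makes the exact and
graph-based search paths rank-consistent on the same representation.
Out-of-vocabulary words are skipped and counted; an all-out-of-vocabulary
spectrum is an error naming the offending id.

**Training determinism.** The C++ trainer is single-threaded, visits
documents in corpus order, and draws all randomness (weight
initialization, negative samples) from a package-owned splitmix64 stream,
so a fixed seed reproduces vectors bit-for-bit. The learning rate is
constant within an epoch and steps down per epoch, floored at
$10^{-4}\,\mathrm{lr}_0$. The unigram table for negative sampling uses
the standard $f^{3/4}$ smoothing; vocabulary order is frequency-desc,
ties alphabetical, so vocabulary indices are reproducible.

## The HNSW index

The index is a layered proximity graph written from scratch. A new
element draws level $l = \lfloor -\ln(u)\, m_L \rfloor$, giving the
survival law $P(l \ge k) = e^{-k/m_L}$; $m_L$ defaults to $1/\ln M$. Note
that the mean of the *floored* level is $1/(e^{1/m_L} - 1)$, not $m_L$;
the underlying exponential draw has mean exactly $m_L$, and
`assignLevel(raw = TRUE)` exposes those draws from the identical RNG
stream so the law can be tested against its closed form.

Insertion descends greedily (candidate list 1) to the element's level,
then searches each layer down to 0 with the `efConstruction`-wide dynamic
candidate list, linking the element to selected neighbours. Three
design choices were open and are fixed as follows:

* *Neighbour selection* uses the spread-preserving heuristic: a candidate
  is kept only if it is closer to the inserted point than to every
  already-kept neighbour; plain closest-M is a configuration fallback.
  The selection itself does not pad back to M — rejected candidates stay
  rejected.
* *Link budget.* A new element may link up to the layer cap: $2M$ on
  layer 0, $M$ above. This follows the FAISS HNSW convention rather than
  the always-M alternative and measurably improves recall at fixed `ef`.
* *Strict bidirectionality.* Every edge is kept symmetric at all times:
  when pruning an overfull neighbour list, reverse links of evicted
  neighbours are removed too, and the eviction pass pads the heuristic's
  selection back to the cap with the nearest discarded candidates so as
  few edges as possible are severed. Popular C++ implementations instead
  leave asymmetric edges behind; symmetry was chosen here because it
  makes the graph auditable with three simple invariants (bidirectional
  edges, degree bounds $M$/$2M$, layer membership $0..l$) that
  `hnswAudit()` verifies after any insertion sequence.

Search descends with candidate list 1 through layers $L..1$ and runs the
full search-layer pass with user `ef` on layer 0, returning the $K \le ef$
nearest by squared Euclidean distance. Distance ties break by insertion
order everywhere, so fixed seed + fixed insertion order gives
bit-identical indexes and searches. Production parameters are $M = 64$,
`efConstruction` 600, `ef` 300; benchmarks in this package use
$M = 16$, `efConstruction` 200, `ef` 100 on 10,000 random 64-d unit
vectors, where mean recall@10 against the brute-force oracle exceeds
0.95. Every distance evaluation is counted, which is how the tests show
sublinear query-cost growth (1k to 64k vectors) without asserting
wall-clock times.

Persistence is a versioned JSON container: parameters, the RNG state (as
a decimal string — a double would corrupt the low bits of the 64-bit
state and desynchronize later level draws), vectors at 17 significant
digits, levels, and the adjacency flattened to a (node, layer, neighbour)
edge table that survives JSON shape simplification. Load reconstructs the
graph exactly; searches and subsequent insertions continue
bit-identically.

## Library preparation

In-silico libraries are assembled from structure databases under five
rules: molecular mass strictly below 1000 Da; elements within
{H, C, O, N, P, S, Cl, F, Br, I, Si}; not ionic; logP within $[-12, 24]$
inclusive; and deduplication, first within a dataset and then strictly
across datasets in priority order (a molecule in an earlier dataset is
removed from all later ones, so the union is disjoint and composite set
sizes are sums of component sizes). Descriptors come from Open Babel:
average molecular weight (the natural reading of "molecular mass" as
listed in source databases; the bound is exclusive as stated), a
Crippen-type logP with inclusive bounds, and the molecular formula for
the element check. "Ionic" is operationalized as any nonzero formal
charge after sanitization (read from the InChI charge/proton layers) or a
charged multi-fragment salt. The identity key is the full 27-character
InChIKey, robust to SMILES representation differences; canonical-SMILES
equality is available as an alternative.

## Matching, mass filter and evaluation

A query retrieves $K$ candidates (default 100) by its variant's
representation and search; output always carries cosine similarity
whatever the internal metric. The optional mass filter then keeps
candidates with $|MW - MW_q| \le$ 5 Da (inclusive boundary) and re-ranks
survivors positionally; it is applied after retrieval, to the top-$K$
list, with $K$ large enough that filtering has headroom. Candidates
lacking a mass are excluded and counted rather than raising an error.

recall@k is the fraction of queries whose true *molecule* key appears
among the top-k candidates; matching on molecule keys rather than
spectrum ids means replicate spectra of one molecule count as correct.
Queries whose truth is absent from the library are warned about and
counted separately instead of silently deflating recall. Library
expansion is strictly incremental: new vectors are inserted into the
existing graph with no rebuild, and prior entries are untouched.

## The synthetic generator

Licensed spectral databases cannot ship with the package, so the
generator emulates the statistical structure the method relies on, with
defaults chosen once as the benchmark condition:

* 2000 molecules, integer m/z in 50–500, Poisson(30) peaks per spectrum
  (floored at 3, exactly-k distinct peaks by construction), Pareto(1.2)
  intensities normalized to the base peak, metadata mass a few Da above
  the heaviest fragment;
* a 300-fragment shared pool organized into molecule classes (one class
  per ~25 molecules, 12-fragment signatures): class fragments co-occur
  across molecules of a class, giving the embedding a co-occurrence
  structure to learn, while private fragments keep molecules separable;
* each pool fragment has an alternative m/z 1–2 Da away; a molecule's
  spectrum uses one of the two positions at random, so both positions
  appear corpus-wide with the same companion fragments.

The measured-vs-predicted gap is a perturbation with four channels:
multiplicative log-normal intensity jitter (sd 0.25), peak dropout
(probability 0.08, never below one peak), spurious low-intensity peaks
(Poisson mean 2), and position swaps (probability 0.45 that a pool peak
flips to its alternative m/z). The swap channel is the deliberate analogue
of systematic peak-position differences between predicted and measured
spectra: embeddings absorb it because the two positions have nearby word
vectors, while binned vectors see an orthogonal change. The noise budget
is weighted toward swaps precisely so this mechanism — not generic
additive noise that degrades both representations equally — drives the
embedding-vs-binning comparison; under these defaults the median WCS
between a spectrum and its perturbed copy sits in the 0.7–0.95 band
typical of predicted-vs-measured EI spectra, and the embedding variants
match or beat the binned variants at recall@10 across generator seeds.

What the generator does *not* emulate: fragmentation chemistry, isotope
patterns, neutral-loss relationships between fragments of one molecule,
and the long-range intensity biases of real prediction models. Passing
tests therefore demonstrate that the pipeline's machinery behaves as
designed under the stated statistical structure, not that any particular
accuracy level transfers to real libraries.

## Numerical choices and degenerate inputs

* All internal intensities live in $[0, 1]$; duplicate m/z merge by
  summation (conserving total ion signal), never by maximum.
* Peaks beyond `maxMz` are dropped with a counter, not an error; an
  empty-after-filtering spectrum is an error.
* Cosine of a zero vector, empty libraries, $K >$ library size,
  $K > ef$, duplicate ids and dimension mismatches are hard errors.
* JSON persistence writes doubles at 17 significant digits so
  write-then-read is bit-exact.
* Test problem sizes: 2000-molecule libraries with 64-d, 10-epoch
  embeddings for pipeline benchmarks; 10k vectors for index quality; 1k
  and 64k for the scaling trend; 100k draws for the level law. These are
  the package's benchmark conditions, stated here so results are
  reproducible as printed.

## Known limitations

* The WCS exponents default to $(a, b) = (0.5, 2)$; other published
  exponent pairs change absolute similarities (though rarely rankings)
  and should be set explicitly when comparing against external tools.
* The HNSW index supports insertion and search, not deletion or
  re-balancing; multithreaded construction is out of scope and
  determinism is only guaranteed for sequential single-threaded use.
* CBOW training at production scale (millions of documents, d = 500,
  60 epochs) is compute-heavy in a single thread; the implementation is
  written for correctness and reproducibility first.
* Descriptor values (MW, logP) follow Open Babel's models; other
  toolkits differ in the third decimal and occasionally in ionic
  perception for exotic salts.
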
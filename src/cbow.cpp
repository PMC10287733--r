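// Single-threaded word2vec trainer (CBOW and skip-gram) with negative
// sampling, written for peak-word corpora where the context window spans
// the whole document. Deterministic: all randomness (weight init, negative
// draws) comes from one splitmix64 stream seeded by the caller, and
// documents are visited in corpus order.
//
// The caller passes documents as 0-based word-index vectors over a fixed
// vocabulary plus per-word corpus frequencies; the input (word) matrix is
// returned. Learning rate is constant within an epoch and decays by a
// fixed amount per epoch, floored at lr0/10000.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

#include "rng.h"

using namespace Rcpp;

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;

// unigram table for negative sampling, frequencies raised to 3/4
std::vector<int> buildUnigramTable(const std::vector<double>& freq,
                                   int tableSize) {
    std::vector<int> table(tableSize);
    double total = 0.0;
    const double power = 0.75;
    for (double f : freq) total += std::pow(f, power);
    size_t i = 0;
    double cum = std::pow(freq[0], power) / total;
    for (int a = 0; a < tableSize; ++a) {
        table[a] = static_cast<int>(i);
        if (static_cast<double>(a) / tableSize > cum && i + 1 < freq.size()) {
            ++i;
            cum += std::pow(freq[i], power) / total;
        }
    }
    return table;
}

}  // namespace

// [[Rcpp::export(name = ".w2v_train")]]
NumericMatrix w2v_train(List docs, NumericVector freq, int dim, int window,
                        bool cbow, int negative, double lr0, double lrDecay,
                        int epochs, double seed) {
    int vocab = freq.size();
    if (vocab < 1) stop("empty vocabulary");
    if (dim < 1) stop("dim must be >= 1");
    if (negative < 1) stop("negative sampling requires negative >= 1");

    std::vector<double> freqV(freq.begin(), freq.end());
    int tableSize = std::max(1000000, vocab * 20);
    std::vector<int> unigram = buildUnigramTable(freqV, tableSize);

    std::vector<double> expTable(EXP_TABLE_SIZE);
    for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
        double x = std::exp((i / static_cast<double>(EXP_TABLE_SIZE) * 2 - 1) *
                            MAX_EXP);
        expTable[i] = x / (x + 1.0);
    }
    auto sigmoid = [&](double f) {
        if (f > MAX_EXP) return 1.0;
        if (f < -MAX_EXP) return 0.0;
        return expTable[static_cast<int>((f + MAX_EXP) *
                                         (EXP_TABLE_SIZE / MAX_EXP / 2))];
    };

    SplitMix64 rng(static_cast<uint64_t>(seed));

    // syn0: input (word) vectors, uniform in [-0.5, 0.5)/dim; syn1: output
    // (context-prediction) weights, zero-initialized as in word2vec
    std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
    std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
    for (size_t i = 0; i < syn0.size(); ++i)
        syn0[i] = (rng.unif() - 0.5) / dim;

    int ndocs = docs.size();
    std::vector<std::vector<int> > corpus(ndocs);
    for (int d = 0; d < ndocs; ++d) {
        IntegerVector w = docs[d];
        corpus[d].assign(w.begin(), w.end());
        for (int idx : corpus[d])
            if (idx < 0 || idx >= vocab) stop("word index out of vocabulary");
    }

    std::vector<double> h(dim), e(dim);

    for (int epoch = 0; epoch < epochs; ++epoch) {
        double lr = lr0 - epoch * lrDecay;
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        for (int d = 0; d < ndocs; ++d) {
            const std::vector<int>& doc = corpus[d];
            int len = static_cast<int>(doc.size());
            if (len < 2) continue;
            for (int pos = 0; pos < len; ++pos) {
                int center = doc[pos];
                int lo = std::max(0, pos - window);
                int hi = std::min(len - 1, pos + window);

                if (cbow) {
                    std::fill(h.begin(), h.end(), 0.0);
                    std::fill(e.begin(), e.end(), 0.0);
                    int cw = 0;
                    for (int p = lo; p <= hi; ++p) {
                        if (p == pos) continue;
                        const double* v0 =
                            &syn0[static_cast<size_t>(doc[p]) * dim];
                        for (int k = 0; k < dim; ++k) h[k] += v0[k];
                        ++cw;
                    }
                    if (cw == 0) continue;
                    for (int k = 0; k < dim; ++k) h[k] /= cw;  // CBOW mean
                    for (int s = 0; s < negative + 1; ++s) {
                        int target;
                        double label;
                        if (s == 0) {
                            target = center;
                            label = 1.0;
                        } else {
                            target = unigram[rng.next() % tableSize];
                            if (target == center) continue;
                            label = 0.0;
                        }
                        double* v1 = &syn1[static_cast<size_t>(target) * dim];
                        double f = 0.0;
                        for (int k = 0; k < dim; ++k) f += h[k] * v1[k];
                        double g = (label - sigmoid(f)) * lr;
                        for (int k = 0; k < dim; ++k) {
                            e[k] += g * v1[k];
                            v1[k] += g * h[k];
                        }
                    }
                    for (int p = lo; p <= hi; ++p) {
                        if (p == pos) continue;
                        double* v0 = &syn0[static_cast<size_t>(doc[p]) * dim];
                        for (int k = 0; k < dim; ++k) v0[k] += e[k];
                    }
                } else {  // skip-gram
                    for (int p = lo; p <= hi; ++p) {
                        if (p == pos) continue;
                        double* v0 = &syn0[static_cast<size_t>(doc[p]) * dim];
                        std::fill(e.begin(), e.end(), 0.0);
                        for (int s = 0; s < negative + 1; ++s) {
                            int target;
                            double label;
                            if (s == 0) {
                                target = center;
                                label = 1.0;
                            } else {
                                target = unigram[rng.next() % tableSize];
                                if (target == center) continue;
                                label = 0.0;
                            }
                            double* v1 =
                                &syn1[static_cast<size_t>(target) * dim];
                            double f = 0.0;
                            for (int k = 0; k < dim; ++k) f += v0[k] * v1[k];
                            double g = (label - sigmoid(f)) * lr;
                            for (int k = 0; k < dim; ++k) {
                                e[k] += g * v1[k];
                                v1[k] += g * v0[k];
                            }
                        }
                        for (int k = 0; k < dim; ++k) v0[k] += e[k];
                    }
                }
            }
        }
        Rcpp::checkUserInterrupt();
    }

    NumericMatrix out(vocab, dim);
    for (int i = 0; i < vocab; ++i)
        for (int k = 0; k < dim; ++k)
            out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
    return out;
}
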
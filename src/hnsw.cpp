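// Hierarchical navigable small-world (HNSW) proximity graph, written from
// scratch: multi-layer graph, greedy search-layer routine with a dynamic
// candidate list, insertion with bidirectional M-linking and heuristic
// neighbour selection, kNN query, and full serialization to plain R lists.
//
// Distances are squared Euclidean; callers L2-normalize vectors upstream so
// the ranking coincides with cosine ranking. All randomness comes from a
// package-owned splitmix64 stream, so a fixed seed gives a bit-identical
// index regardless of R's RNG state. Ties in distance are broken by
// insertion order throughout.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <string>
#include <unordered_map>
#include <vector>

#include "rng.h"

using namespace Rcpp;

namespace {

// (distance, node) pair; all heap orderings tie-break on node id so the
// traversal is deterministic.
struct Cand {
    double dist;
    int node;
};
struct NearestFirst {  // min-heap on distance
    bool operator()(const Cand& a, const Cand& b) const {
        if (a.dist != b.dist) return a.dist > b.dist;
        return a.node > b.node;
    }
};
struct FarthestFirst {  // max-heap on distance
    bool operator()(const Cand& a, const Cand& b) const {
        if (a.dist != b.dist) return a.dist < b.dist;
        return a.node < b.node;
    }
};

typedef std::priority_queue<Cand, std::vector<Cand>, NearestFirst> MinHeap;
typedef std::priority_queue<Cand, std::vector<Cand>, FarthestFirst> MaxHeap;

class HNSW {
  public:
    int dim;
    int M, M0, efConstruction, efDefault;
    double mL;
    uint64_t seed;
    bool heuristic;  // neighbour selection: heuristic vs closest-M

    std::vector<std::string> ids;
    std::unordered_map<std::string, int> id2pos;
    std::vector<double> data;             // row-major n x dim
    std::vector<int> levels;              // level of each node
    std::vector<std::vector<std::vector<int> > > links;  // [node][layer]
    int entry;
    int maxLevel;
    SplitMix64 rng;
    long long distEvals;
    mutable std::vector<int> visitedMark;
    mutable int visitedEpoch;

    HNSW(int dim_, int M_, int efc_, int ef_, double mL_, uint64_t seed_,
         bool heuristic_)
        : dim(dim_), M(M_), M0(2 * M_), efConstruction(efc_), efDefault(ef_),
          mL(mL_), seed(seed_), heuristic(heuristic_), entry(-1), maxLevel(-1),
          rng(seed_), distEvals(0), visitedEpoch(0) {}

    int size() const { return static_cast<int>(ids.size()); }

    double distance(const double* q, int node) {
        ++distEvals;
        const double* v = &data[static_cast<size_t>(node) * dim];
        double s = 0.0;
        for (int k = 0; k < dim; ++k) {
            double d = q[k] - v[k];
            s += d * d;
        }
        return s;
    }

    int maxNeighbors(int layer) const { return layer == 0 ? M0 : M; }

    // Greedy best-first search of one layer with a dynamic candidate list
    // of size ef. Returns up to ef nearest found, nearest first.
    std::vector<Cand> searchLayer(const double* q,
                                  const std::vector<Cand>& entries, int ef,
                                  int layer) {
        std::vector<Cand> out;
        if (entries.empty()) return out;

        if (static_cast<int>(visitedMark.size()) < size())
            visitedMark.resize(size(), 0);
        ++visitedEpoch;

        MinHeap frontier;  // candidates to expand, nearest first
        MaxHeap results;   // best ef found so far, farthest on top
        for (const Cand& e : entries) {
            if (visitedMark[e.node] == visitedEpoch) continue;
            visitedMark[e.node] = visitedEpoch;
            frontier.push(e);
            results.push(e);
            if (static_cast<int>(results.size()) > ef) results.pop();
        }

        while (!frontier.empty()) {
            Cand c = frontier.top();
            frontier.pop();
            if (static_cast<int>(results.size()) >= ef &&
                c.dist > results.top().dist)
                break;  // nearest unexpanded is worse than worst retained
            const std::vector<int>& nb =
                links[c.node][static_cast<size_t>(layer)];
            for (int v : nb) {
                if (visitedMark[v] == visitedEpoch) continue;
                visitedMark[v] = visitedEpoch;
                double d = distance(q, v);
                if (static_cast<int>(results.size()) < ef ||
                    d < results.top().dist) {
                    frontier.push(Cand{d, v});
                    results.push(Cand{d, v});
                    if (static_cast<int>(results.size()) > ef) results.pop();
                }
            }
        }
        out.reserve(results.size());
        while (!results.empty()) {
            out.push_back(results.top());
            results.pop();
        }
        std::reverse(out.begin(), out.end());  // nearest first
        return out;
    }

    // Neighbour selection. The heuristic keeps a candidate only if it is
    // closer to the query than to every already-kept neighbour, which
    // preserves links in different directions; closest-M is the plain
    // alternative.
    std::vector<int> selectNeighbors(const double* q, std::vector<Cand> cand,
                                     int m) {
        std::sort(cand.begin(), cand.end(), [](const Cand& a, const Cand& b) {
            if (a.dist != b.dist) return a.dist < b.dist;
            return a.node < b.node;
        });
        std::vector<int> kept;
        if (!heuristic) {
            for (const Cand& c : cand) {
                kept.push_back(c.node);
                if (static_cast<int>(kept.size()) >= m) break;
            }
            return kept;
        }
        for (const Cand& c : cand) {
            if (static_cast<int>(kept.size()) >= m) break;
            bool ok = true;
            const double* vc = &data[static_cast<size_t>(c.node) * dim];
            for (int k : kept) {
                if (distance(vc, k) < c.dist) {
                    ok = false;
                    break;
                }
            }
            if (ok) kept.push_back(c.node);
        }
        return kept;
    }

    void pruneNode(int node, int layer) {
        std::vector<int>& nb = links[node][static_cast<size_t>(layer)];
        int cap = maxNeighbors(layer);
        if (static_cast<int>(nb.size()) <= cap) return;
        const double* vq = &data[static_cast<size_t>(node) * dim];
        std::vector<Cand> cand;
        cand.reserve(nb.size());
        for (int v : nb) cand.push_back(Cand{distance(vq, v), v});
        std::vector<int> kept = selectNeighbors(vq, cand, cap);
        // keep pruned connections: pad back to cap with the nearest
        // discarded candidates so pruning severs as few edges as possible
        if (static_cast<int>(kept.size()) < cap) {
            std::sort(cand.begin(), cand.end(),
                      [](const Cand& a, const Cand& b) {
                          if (a.dist != b.dist) return a.dist < b.dist;
                          return a.node < b.node;
                      });
            for (const Cand& c : cand) {
                if (static_cast<int>(kept.size()) >= cap) break;
                if (std::find(kept.begin(), kept.end(), c.node) == kept.end())
                    kept.push_back(c.node);
            }
        }
        // drop reverse links of pruned-away neighbours to keep all edges
        // bidirectional
        for (int v : nb) {
            if (std::find(kept.begin(), kept.end(), v) != kept.end()) continue;
            std::vector<int>& rev = links[v][static_cast<size_t>(layer)];
            rev.erase(std::remove(rev.begin(), rev.end(), node), rev.end());
        }
        nb = kept;
    }

    int drawLevel() { return static_cast<int>(std::floor(-std::log(rng.unif()) * mL)); }

    void insert(const std::string& id, const double* v) {
        if (id2pos.count(id))
            stop("duplicate id in HNSW index: '%s'", id.c_str());
        int node = size();
        ids.push_back(id);
        id2pos[id] = node;
        data.insert(data.end(), v, v + dim);
        int l = drawLevel();
        levels.push_back(l);
        links.push_back(std::vector<std::vector<int> >(
            static_cast<size_t>(l) + 1));

        if (entry < 0) {  // first element becomes the entry point
            entry = node;
            maxLevel = l;
            return;
        }

        const double* q = &data[static_cast<size_t>(node) * dim];
        Cand ep{distance(q, entry), entry};
        // greedy descent through layers above l
        for (int lc = maxLevel; lc > l; --lc) {
            std::vector<Cand> res =
                searchLayer(q, std::vector<Cand>(1, ep), 1, lc);
            if (!res.empty()) ep = res[0];
        }
        // insert with efConstruction search from min(l, maxLevel) down to 0
        std::vector<Cand> eps(1, ep);
        for (int lc = std::min(l, maxLevel); lc >= 0; --lc) {
            std::vector<Cand> W = searchLayer(q, eps, efConstruction, lc);
            // layer 0 allows M0 = 2M links, so select up to the layer cap
            std::vector<int> nbs = selectNeighbors(q, W, maxNeighbors(lc));
            for (int nb : nbs) {
                links[node][static_cast<size_t>(lc)].push_back(nb);
                links[nb][static_cast<size_t>(lc)].push_back(node);
                pruneNode(nb, lc);
            }
            eps = W;
        }
        if (l > maxLevel) {
            maxLevel = l;
            entry = node;
        }
    }

    // kNN query: ef=1 greedy descent through layers L..1, then a full
    // search-layer pass with user ef on layer 0.
    std::vector<Cand> knn(const double* q, int K, int ef) {
        if (entry < 0) stop("empty HNSW index");
        if (K > ef) stop("K must not exceed ef");
        Cand ep{distance(q, entry), entry};
        for (int lc = maxLevel; lc >= 1; --lc) {
            std::vector<Cand> res =
                searchLayer(q, std::vector<Cand>(1, ep), 1, lc);
            if (!res.empty()) ep = res[0];
        }
        std::vector<Cand> W =
            searchLayer(q, std::vector<Cand>(1, ep), ef, 0);
        if (static_cast<int>(W.size()) > K) W.resize(K);
        return W;
    }
};

HNSW* get(SEXP xp) {
    Rcpp::XPtr<HNSW> p(xp);
    if (!p) stop("invalid HNSW pointer");
    return p.get();
}

}  // namespace

// [[Rcpp::export(name = ".hnsw_create")]]
SEXP hnsw_create(int dim, int M, int efConstruction, int ef, double mL,
                 double seed, bool heuristic) {
    if (dim < 1) stop("dim must be >= 1");
    if (M < 2) stop("M must be >= 2");
    if (efConstruction < M) stop("efConstruction must be >= M");
    if (ef < 1) stop("ef must be >= 1");
    if (!(mL > 0)) stop("mL must be > 0");
    HNSW* h = new HNSW(dim, M, efConstruction, ef, mL,
                       static_cast<uint64_t>(seed), heuristic);
    return Rcpp::XPtr<HNSW>(h, true);
}

// [[Rcpp::export(name = ".hnsw_insert")]]
void hnsw_insert(SEXP xp, CharacterVector ids, NumericMatrix x) {
    HNSW* h = get(xp);
    if (x.ncol() != h->dim)
        stop("vector dimension %d does not match index dimension %d",
             x.ncol(), h->dim);
    if (ids.size() != x.nrow()) stop("ids and rows differ in length");
    std::vector<double> row(h->dim);
    for (int i = 0; i < x.nrow(); ++i) {
        for (int k = 0; k < h->dim; ++k) row[k] = x(i, k);
        h->insert(as<std::string>(ids[i]), row.data());
    }
}

// [[Rcpp::export(name = ".hnsw_search")]]
List hnsw_search(SEXP xp, NumericMatrix q, int K, int ef) {
    HNSW* h = get(xp);
    if (q.ncol() != h->dim)
        stop("query dimension %d does not match index dimension %d",
             q.ncol(), h->dim);
    int nq = q.nrow();
    List idsOut(nq);
    List distOut(nq);
    std::vector<double> row(h->dim);
    for (int i = 0; i < nq; ++i) {
        for (int k = 0; k < h->dim; ++k) row[k] = q(i, k);
        std::vector<Cand> res = h->knn(row.data(), K, ef);
        CharacterVector rid(res.size());
        NumericVector rd(res.size());
        for (size_t j = 0; j < res.size(); ++j) {
            rid[j] = h->ids[res[j].node];
            rd[j] = res[j].dist;
        }
        idsOut[i] = rid;
        distOut[i] = rd;
    }
    return List::create(_["ids"] = idsOut, _["distances"] = distOut);
}

// [[Rcpp::export(name = ".hnsw_size")]]
int hnsw_size(SEXP xp) { return get(xp)->size(); }

// [[Rcpp::export(name = ".hnsw_info")]]
List hnsw_info(SEXP xp) {
    HNSW* h = get(xp);
    return List::create(
        _["dim"] = h->dim, _["M"] = h->M, _["M0"] = h->M0,
        _["efConstruction"] = h->efConstruction, _["ef"] = h->efDefault,
        _["mL"] = h->mL, _["seed"] = static_cast<double>(h->seed),
        _["heuristic"] = h->heuristic, _["count"] = h->size(),
        _["maxLevel"] = h->maxLevel,
        _["entry"] = h->entry < 0 ? NA_STRING
                                  : String(h->ids[h->entry]));
}

// [[Rcpp::export(name = ".hnsw_dist_evals")]]
double hnsw_dist_evals(SEXP xp, bool reset) {
    HNSW* h = get(xp);
    double n = static_cast<double>(h->distEvals);
    if (reset) h->distEvals = 0;
    return n;
}

// Full graph dump for structural audits: levels, per-layer adjacency
// (1-based positions), entry point, ids.
// [[Rcpp::export(name = ".hnsw_graph")]]
List hnsw_graph(SEXP xp) {
    HNSW* h = get(xp);
    int n = h->size();
    IntegerVector lev(n);
    for (int i = 0; i < n; ++i) lev[i] = h->levels[i];
    List adj(h->maxLevel + 1);
    for (int layer = 0; layer <= h->maxLevel; ++layer) {
        List layerAdj(n);
        for (int i = 0; i < n; ++i) {
            if (h->levels[i] >= layer) {
                const std::vector<int>& nb =
                    h->links[i][static_cast<size_t>(layer)];
                IntegerVector v(nb.size());
                for (size_t j = 0; j < nb.size(); ++j) v[j] = nb[j] + 1;
                layerAdj[i] = v;
            } else {
                layerAdj[i] = R_NilValue;
            }
        }
        adj[layer] = layerAdj;
    }
    CharacterVector ids(n);
    for (int i = 0; i < n; ++i) ids[i] = h->ids[i];
    return List::create(_["ids"] = ids, _["levels"] = lev,
                        _["layers"] = adj,
                        _["entry"] = h->entry + 1,
                        _["maxLevel"] = h->maxLevel);
}

// [[Rcpp::export(name = ".hnsw_serialize")]]
List hnsw_serialize(SEXP xp) {
    HNSW* h = get(xp);
    int n = h->size();
    NumericMatrix vec(n, h->dim);
    for (int i = 0; i < n; ++i)
        for (int k = 0; k < h->dim; ++k)
            vec(i, k) = h->data[static_cast<size_t>(i) * h->dim + k];
    IntegerVector lev(n);
    for (int i = 0; i < n; ++i) lev[i] = h->levels[i];
    CharacterVector ids(n);
    for (int i = 0; i < n; ++i) ids[i] = h->ids[i];
    // flatten adjacency: per node, per layer, neighbour runs
    List allLinks(n);
    for (int i = 0; i < n; ++i) {
        List nodeLinks(h->levels[i] + 1);
        for (int layer = 0; layer <= h->levels[i]; ++layer) {
            const std::vector<int>& nb =
                h->links[i][static_cast<size_t>(layer)];
            IntegerVector v(nb.size());
            for (size_t j = 0; j < nb.size(); ++j) v[j] = nb[j] + 1;
            nodeLinks[layer] = v;
        }
        allLinks[i] = nodeLinks;
    }
    return List::create(
        _["dim"] = h->dim, _["M"] = h->M,
        _["efConstruction"] = h->efConstruction, _["ef"] = h->efDefault,
        _["mL"] = h->mL, _["seed"] = static_cast<double>(h->seed),
        _["heuristic"] = h->heuristic,
        // full 64-bit state as a decimal string: a double would lose the
        // low bits and desynchronize later level draws
        _["rngState"] = std::to_string(h->rng.state),
        _["entry"] = h->entry + 1, _["maxLevel"] = h->maxLevel,
        _["ids"] = ids, _["levels"] = lev, _["vectors"] = vec,
        _["links"] = allLinks);
}

// [[Rcpp::export(name = ".hnsw_deserialize")]]
SEXP hnsw_deserialize(List s) {
    HNSW* h = new HNSW(as<int>(s["dim"]), as<int>(s["M"]),
                       as<int>(s["efConstruction"]), as<int>(s["ef"]),
                       as<double>(s["mL"]),
                       static_cast<uint64_t>(as<double>(s["seed"])),
                       as<bool>(s["heuristic"]));
    {
        // manual decimal parse: keeps the full 64-bit state exact
        uint64_t st = 0;
        for (char c : as<std::string>(s["rngState"]))
            if (c >= '0' && c <= '9') st = st * 10u + (c - '0');
        h->rng.state = st;
    }
    CharacterVector ids = s["ids"];
    IntegerVector lev = s["levels"];
    NumericMatrix vec = s["vectors"];
    List allLinks = s["links"];
    int n = ids.size();
    h->ids.resize(n);
    h->levels.resize(n);
    h->data.resize(static_cast<size_t>(n) * h->dim);
    h->links.resize(n);
    for (int i = 0; i < n; ++i) {
        h->ids[i] = as<std::string>(ids[i]);
        h->id2pos[h->ids[i]] = i;
        h->levels[i] = lev[i];
        for (int k = 0; k < h->dim; ++k)
            h->data[static_cast<size_t>(i) * h->dim + k] = vec(i, k);
        List nodeLinks = allLinks[i];
        h->links[i].resize(static_cast<size_t>(lev[i]) + 1);
        for (int layer = 0; layer <= lev[i]; ++layer) {
            IntegerVector v = nodeLinks[layer];
            std::vector<int>& nb = h->links[i][static_cast<size_t>(layer)];
            nb.resize(v.size());
            for (int j = 0; j < v.size(); ++j) nb[j] = v[j] - 1;
        }
    }
    h->entry = as<int>(s["entry"]) - 1;
    h->maxLevel = as<int>(s["maxLevel"]);
    return Rcpp::XPtr<HNSW>(h, true);
}

// Level assignment l = floor(-ln(u) * mL). With raw = TRUE the underlying
// exponential draws (mean mL) are returned from the identical RNG stream.
// [[Rcpp::export(name = ".hnsw_assign_levels")]]
NumericVector hnsw_assign_levels(int n, double mL, double seed, bool raw) {
    if (!(mL >= 0)) stop("mL must be >= 0");
    SplitMix64 rng(static_cast<uint64_t>(seed));
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double x = mL > 0 ? -std::log(rng.unif()) * mL : 0.0;
        out[i] = raw ? x : std::floor(x);
    }
    return out;
}
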
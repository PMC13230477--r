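// Hierarchical navigable small world graph over unit-norm embeddings,
// inner-product metric (= cosine on unit vectors).  Level assignment uses a
// seeded mt19937 so a rebuild from the same inputs is bit-identical.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Hnsw {
  int dim = 0;
  int M = 32;            // graph degree on upper layers
  int Mmax0 = 64;        // degree cap on layer 0
  int ef_construction = 200;
  double level_mult = 1.0;
  std::vector<double> data;                        // n * dim, row-major
  std::vector<int> levels;                         // per-node top level
  std::vector<std::vector<std::vector<int>>> nbr;  // [node][level] -> ids
  int entry = -1;
  int max_level = -1;
  std::mt19937 rng;

  double sim(int a, const double* q) const {
    const double* p = &data[(size_t)a * dim];
    double s = 0.0;
    for (int d = 0; d < dim; ++d) s += p[d] * q[d];
    return s;
  }

  // Beam search on one layer; returns up to `ef` candidates (unordered heap
  // content) closest to q by inner product.
  std::vector<std::pair<double, int>> search_layer(
      const double* q, int ep, int ef, int level,
      std::vector<int>& visited, int stamp) const {
    // max-heap of frontier by similarity, min-heap of kept results
    std::priority_queue<std::pair<double, int>> frontier;
    std::priority_queue<std::pair<double, int>,
                        std::vector<std::pair<double, int>>,
                        std::greater<std::pair<double, int>>> kept;
    double s0 = sim(ep, q);
    frontier.push({s0, ep});
    kept.push({s0, ep});
    visited[ep] = stamp;
    while (!frontier.empty()) {
      auto cur = frontier.top();
      frontier.pop();
      if (!kept.empty() && cur.first < kept.top().first &&
          (int)kept.size() >= ef)
        break;
      for (int e : nbr[cur.second][level]) {
        if (visited[e] == stamp) continue;
        visited[e] = stamp;
        double s = sim(e, q);
        if ((int)kept.size() < ef || s > kept.top().first) {
          frontier.push({s, e});
          kept.push({s, e});
          if ((int)kept.size() > ef) kept.pop();
        }
      }
    }
    std::vector<std::pair<double, int>> out;
    out.reserve(kept.size());
    while (!kept.empty()) { out.push_back(kept.top()); kept.pop(); }
    return out;
  }

  // Diversity-aware neighbour selection (the HNSW paper's heuristic):
  // a candidate is kept only if it is closer to the base point than to any
  // already-kept neighbour; slots left over are backfilled by similarity.
  // Plain top-M selection degenerates on tightly clustered data (all links
  // stay inside a cluster and the graph loses its long-range edges).
  std::vector<int> select_neighbors(const double* base,
                                    std::vector<std::pair<double, int>> cand,
                                    int max_deg) const {
    std::sort(cand.begin(), cand.end(),
              [](const std::pair<double, int>& a,
                 const std::pair<double, int>& b) { return a.first > b.first; });
    std::vector<int> kept;
    std::vector<char> used(cand.size(), 0);
    for (size_t i = 0; i < cand.size(); ++i) {
      if ((int)kept.size() >= max_deg) break;
      const double* pc = &data[(size_t)cand[i].second * dim];
      bool diverse = true;
      for (int r : kept) {
        if (sim(r, pc) > cand[i].first) { diverse = false; break; }
      }
      if (diverse) { kept.push_back(cand[i].second); used[i] = 1; }
    }
    for (size_t i = 0; i < cand.size() && (int)kept.size() < max_deg; ++i)
      if (!used[i]) kept.push_back(cand[i].second);
    return kept;
  }

  void connect(int node, int level, std::vector<std::pair<double, int>> cand,
               int max_deg) {
    const double* pn = &data[(size_t)node * dim];
    std::vector<int> kept = select_neighbors(pn, cand, max_deg);
    auto& lst = nbr[node][level];
    int cap = (level == 0) ? Mmax0 : M;
    for (int c : kept) {
      lst.push_back(c);
      auto& back = nbr[c][level];
      back.push_back(node);
      if ((int)back.size() > cap) {
        const double* pc = &data[(size_t)c * dim];
        std::vector<std::pair<double, int>> scored;
        scored.reserve(back.size());
        for (int b : back) scored.push_back({sim(b, pc), b});
        back = select_neighbors(pc, scored, cap);
      }
    }
  }

  void insert(const double* q, std::vector<int>& visited, int& stamp) {
    int node = (int)levels.size() - 1;  // caller already appended data/level
    int l = levels[node];
    nbr[node].assign(l + 1, {});
    if (entry < 0) {
      entry = node;
      max_level = l;
      return;
    }
    int ep = entry;
    // greedy descent through layers above l
    for (int lc = max_level; lc > l; --lc) {
      bool moved = true;
      double best = sim(ep, q);
      while (moved) {
        moved = false;
        for (int e : nbr[ep][lc]) {
          double s = sim(e, q);
          if (s > best) { best = s; ep = e; moved = true; }
        }
      }
    }
    for (int lc = std::min(l, max_level); lc >= 0; --lc) {
      ++stamp;
      auto w = search_layer(q, ep, ef_construction, lc, visited, stamp);
      // best candidate becomes entry point for the next layer down
      int best_id = w[0].second;
      double best_s = w[0].first;
      for (auto& c : w)
        if (c.first > best_s) { best_s = c.first; best_id = c.second; }
      connect(node, lc, w, M);
      ep = best_id;
    }
    if (l > max_level) { max_level = l; entry = node; }
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP hnsw_build(NumericMatrix x, int m, int ef_construction, int seed) {
  int n = x.nrow(), dim = x.ncol();
  if (n < 1) stop("cannot build an index over zero slices");
  Hnsw* h = new Hnsw();
  h->dim = dim;
  h->M = m;
  h->Mmax0 = 2 * m;
  h->ef_construction = ef_construction;
  h->level_mult = 1.0 / std::log((double)m);
  h->rng.seed((unsigned)seed);
  h->data.resize((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d) h->data[(size_t)i * dim + d] = x(i, d);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> visited(n, -1);
  int stamp = 0;
  h->nbr.resize(n);
  for (int i = 0; i < n; ++i) {
    double u = unif(h->rng);
    int lvl = (int)std::floor(-std::log(std::max(u, 1e-300)) * h->level_mult);
    h->levels.push_back(lvl);
    h->nbr[i].clear();
    h->insert(&h->data[(size_t)i * dim], visited, stamp);
  }
  XPtr<Hnsw> ptr(h, true);
  return ptr;
}

// [[Rcpp::export]]
List hnsw_query(SEXP index, NumericVector q, int k, int ef_search) {
  XPtr<Hnsw> h(index);
  if ((int)q.size() != h->dim) stop("query dimension mismatch");
  int n = (int)h->levels.size();
  std::vector<double> qq(q.begin(), q.end());
  int ep = h->entry;
  for (int lc = h->max_level; lc > 0; --lc) {
    bool moved = true;
    double best = h->sim(ep, qq.data());
    while (moved) {
      moved = false;
      for (int e : h->nbr[ep][lc]) {
        double s = h->sim(e, qq.data());
        if (s > best) { best = s; ep = e; moved = true; }
      }
    }
  }
  std::vector<int> visited(n, -1);
  int stamp = 1;
  int ef = std::max(ef_search, k);
  auto w = h->search_layer(qq.data(), ep, ef, 0, visited, stamp);
  std::sort(w.begin(), w.end(),
            [](const std::pair<double, int>& a,
               const std::pair<double, int>& b) { return a.first > b.first; });
  int kk = std::min((int)w.size(), k);
  IntegerVector idx(kk);
  NumericVector score(kk);
  for (int i = 0; i < kk; ++i) {
    idx[i] = w[i].second + 1;  // 1-based for R
    score[i] = w[i].first;
  }
  return List::create(_["idx"] = idx, _["score"] = score);
}

// [[Rcpp::export]]
int hnsw_size(SEXP index) {
  XPtr<Hnsw> h(index);
  return (int)h->levels.size();
}
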
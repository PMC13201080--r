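#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <random>
#include <algorithm>
#include <limits>
#include <cmath>
using namespace Rcpp;

// NN-descent k-NN graph construction under cosine distance, with random
// projection tree initialization. Points are the columns of `emb` (d x n,
// rows pre-normalized to unit length by the caller), so each point is
// contiguous in memory. Single-threaded and fully seeded for determinism.

namespace {

inline double cosine_dist(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int i = 0; i < d; ++i) s += a[i] * b[i];
  return 1.0 - s;
}

struct NeighborHeap {
  int n, K;
  std::vector<double> dist;
  std::vector<int> idx;
  std::vector<char> isnew;

  NeighborHeap(int n_, int K_)
      : n(n_), K(K_),
        dist((size_t)n_ * K_, std::numeric_limits<double>::infinity()),
        idx((size_t)n_ * K_, -1),
        isnew((size_t)n_ * K_, 0) {}

  // Max-heap per node on dist[off..off+K). Returns 1 if inserted.
  int push(int u, double d, int j, char flag) {
    size_t off = (size_t)u * K;
    if (d >= dist[off]) return 0;
    for (int i = 0; i < K; ++i)
      if (idx[off + i] == j) return 0;
    dist[off] = d;
    idx[off] = j;
    isnew[off] = flag;
    size_t i = 0;
    while (true) {
      size_t l = 2 * i + 1, r = 2 * i + 2, m = i;
      if (l < (size_t)K && dist[off + l] > dist[off + m]) m = l;
      if (r < (size_t)K && dist[off + r] > dist[off + m]) m = r;
      if (m == i) break;
      std::swap(dist[off + i], dist[off + m]);
      std::swap(idx[off + i], idx[off + m]);
      std::swap(isnew[off + i], isnew[off + m]);
      i = m;
    }
    return 1;
  }
};

struct Sampler {
  std::mt19937 rng;
  explicit Sampler(uint32_t seed) : rng(seed) {}
  int unif(int n) {  // uniform on [0, n)
    return (int)(rng() % (uint32_t)n);
  }
  double unif01() {
    return (double)rng() / 4294967296.0;
  }
};

struct Reservoir {
  // Fixed-capacity reservoir sample per node.
  int cap;
  std::vector<int> items;   // n * cap
  std::vector<int> nseen;   // n
  Reservoir(int n, int cap_) : cap(cap_), items((size_t)n * cap_), nseen(n, 0) {}
  void add(int u, int j, Sampler& s) {
    size_t off = (size_t)u * cap;
    int seen = nseen[u]++;
    if (seen < cap) {
      items[off + seen] = j;
    } else {
      int r = s.unif(seen + 1);
      if (r < cap) items[off + r] = j;
    }
  }
  int size(int u) const { return nseen[u] < cap ? nseen[u] : cap; }
  int get(int u, int i) const { return items[(size_t)u * cap + i]; }
};

void leaf_all_pairs(const std::vector<int>& pts, size_t lo, size_t hi,
                    const double* X, int d, NeighborHeap& heap,
                    const int* forbidden) {
  for (size_t a = lo; a < hi; ++a) {
    for (size_t b = a + 1; b < hi; ++b) {
      int i = pts[a], j = pts[b];
      if (i == j || forbidden[i] == j) continue;
      double dd = cosine_dist(X + (size_t)i * d, X + (size_t)j * d, d);
      heap.push(i, dd, j, 1);
      heap.push(j, dd, i, 1);
    }
  }
}

// Recursively split pts[lo..hi) by a random hyperplane through the midpoint
// of two random points; on degenerate splits fall back to a random halving.
void rp_tree_split(std::vector<int>& pts, size_t lo, size_t hi, const double* X,
                   int d, int leaf_size, NeighborHeap& heap,
                   const int* forbidden, Sampler& s, int depth) {
  size_t n = hi - lo;
  if ((int)n <= leaf_size || depth > 60) {
    leaf_all_pairs(pts, lo, hi, X, d, heap, forbidden);
    return;
  }
  int ia = pts[lo + (size_t)s.unif((int)n)];
  int ib = pts[lo + (size_t)s.unif((int)n)];
  int tries = 0;
  while (ib == ia && ++tries < 8) ib = pts[lo + (size_t)s.unif((int)n)];
  std::vector<double> dir((size_t)d);
  double off = 0.0;
  const double* xa = X + (size_t)ia * d;
  const double* xb = X + (size_t)ib * d;
  for (int i = 0; i < d; ++i) {
    dir[(size_t)i] = xa[i] - xb[i];
    off += dir[(size_t)i] * 0.5 * (xa[i] + xb[i]);
  }
  size_t mid = lo;
  std::vector<int> right;
  right.reserve(n / 2);
  std::vector<int> left;
  left.reserve(n / 2);
  for (size_t t = lo; t < hi; ++t) {
    const double* x = X + (size_t)pts[t] * d;
    double proj = -off;
    for (int i = 0; i < d; ++i) proj += dir[(size_t)i] * x[i];
    bool go_left = proj < 0 || (proj == 0 && s.unif(2) == 0);
    if (go_left) left.push_back(pts[t]); else right.push_back(pts[t]);
  }
  if (left.empty() || right.empty()) {
    // degenerate hyperplane: random halving keeps the recursion bounded
    left.clear(); right.clear();
    for (size_t t = lo; t < hi; ++t)
      (s.unif(2) == 0 ? left : right).push_back(pts[t]);
    if (left.empty() || right.empty()) {
      leaf_all_pairs(pts, lo, hi, X, d, heap, forbidden);
      return;
    }
  }
  for (size_t t = 0; t < left.size(); ++t) pts[lo + t] = left[t];
  mid = lo + left.size();
  for (size_t t = 0; t < right.size(); ++t) pts[mid + t] = right[t];
  rp_tree_split(pts, lo, mid, X, d, leaf_size, heap, forbidden, s, depth + 1);
  rp_tree_split(pts, mid, hi, X, d, leaf_size, heap, forbidden, s, depth + 1);
}

}  // namespace

// [[Rcpp::export]]
List cpp_nndescent(NumericMatrix emb_t, int K, IntegerVector forbidden,
                   int n_trees, int leaf_size, int max_candidates,
                   int max_iter, double tol, int seed) {
  const int d = emb_t.nrow();
  const int n = emb_t.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n - 1) K = n - 1;
  const double* X = REAL(emb_t);
  const int* forb = INTEGER(forbidden);
  Sampler s((uint32_t)seed);
  NeighborHeap heap(n, K);

  // RP-tree initialization
  std::vector<int> pts((size_t)n);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) pts[(size_t)i] = i;
    rp_tree_split(pts, 0, (size_t)n, X, d, leaf_size, heap, forb, s, 0);
  }
  // Random fill for any node whose heap is not yet full
  for (int u = 0; u < n; ++u) {
    size_t off = (size_t)u * K;
    int missing = 0;
    for (int i = 0; i < K; ++i)
      if (heap.idx[off + i] < 0) ++missing;
    int attempts = 2 * (missing + 1);
    while (missing > 0 && attempts-- > 0) {
      int j = s.unif(n);
      if (j == u || forb[u] == j) continue;
      double dd = cosine_dist(X + (size_t)u * d, X + (size_t)j * d, d);
      if (heap.push(u, dd, j, 1)) --missing;
    }
  }

  // NN-descent local join
  int iters_run = 0;
  for (int iter = 0; iter < max_iter; ++iter) {
    ++iters_run;
    Reservoir cand_new(n, max_candidates), cand_old(n, max_candidates);
    for (int u = 0; u < n; ++u) {
      size_t off = (size_t)u * K;
      for (int i = 0; i < K; ++i) {
        int j = heap.idx[off + i];
        if (j < 0) continue;
        if (heap.isnew[off + i]) {
          cand_new.add(u, j, s);
          cand_new.add(j, u, s);
          heap.isnew[off + i] = 0;
        } else {
          cand_old.add(u, j, s);
          cand_old.add(j, u, s);
        }
      }
    }
    long long updates = 0;
    for (int u = 0; u < n; ++u) {
      int nn = cand_new.size(u), no = cand_old.size(u);
      for (int a = 0; a < nn; ++a) {
        int i = cand_new.get(u, a);
        for (int b = a + 1; b < nn; ++b) {
          int j = cand_new.get(u, b);
          if (i == j || forb[i] == j) continue;
          double dd = cosine_dist(X + (size_t)i * d, X + (size_t)j * d, d);
          updates += heap.push(i, dd, j, 1);
          updates += heap.push(j, dd, i, 1);
        }
        for (int b = 0; b < no; ++b) {
          int j = cand_old.get(u, b);
          if (i == j || forb[i] == j) continue;
          double dd = cosine_dist(X + (size_t)i * d, X + (size_t)j * d, d);
          updates += heap.push(i, dd, j, 1);
          updates += heap.push(j, dd, i, 1);
        }
      }
    }
    if ((double)updates <= tol * (double)n * (double)K) break;
  }

  // Emit sorted neighbour lists (ascending distance, ties by index)
  IntegerMatrix out_idx(n, K);
  NumericMatrix out_dist(n, K);
  std::vector<std::pair<double, int> > row((size_t)K);
  for (int u = 0; u < n; ++u) {
    size_t off = (size_t)u * K;
    for (int i = 0; i < K; ++i)
      row[(size_t)i] = std::make_pair(heap.dist[off + i], heap.idx[off + i]);
    std::sort(row.begin(), row.end());
    for (int i = 0; i < K; ++i) {
      if (row[(size_t)i].second < 0) {
        out_idx(u, i) = NA_INTEGER;
        out_dist(u, i) = NA_REAL;
      } else {
        out_idx(u, i) = row[(size_t)i].second + 1;  // 1-based
        out_dist(u, i) = row[(size_t)i].first;
      }
    }
  }
  return List::create(_["idx"] = out_idx, _["dist"] = out_dist,
                      _["iterations"] = iters_run);
}
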
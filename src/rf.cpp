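// Seeded regression random forest: bootstrap resampling, per-node feature
// subsampling (mtry), exhaustive variance-reduction splits, deterministic
// given (data, seed). Kept deliberately small: the forest is a baseline
// whose ensemble spread serves as an uncertainty proxy.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;     // leaf mean
};

// xorshift64* : tiny, portable, deterministic RNG
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_node, max_depth;
  Rng rng;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
          int min_node_, int max_depth_, uint64_t seed)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(seed), feat_pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feat_pool[j] = j;
  }

  int make_leaf(const std::vector<int>& idx) {
    double s = 0.0;
    for (int i : idx) s += y[i];
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(s / idx.size());
    return static_cast<int>(tree.feature.size()) - 1;
  }

  int grow(std::vector<int>& idx, int depth) {
    const int n = static_cast<int>(idx.size());
    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
    const double sse = sum2 - sum * sum / n;
    if (n < 2 * min_node || (max_depth > 0 && depth >= max_depth) || sse <= 1e-12)
      return make_leaf(idx);

    // partial Fisher-Yates for the mtry candidate features
    const int p = static_cast<int>(feat_pool.size());
    const int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j)
      std::swap(feat_pool[j], feat_pool[j + rng.below(p - j)]);

    int best_f = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<std::pair<double, double> > vals(n);
    for (int jj = 0; jj < m; ++jj) {
      const int f = feat_pool[jj];
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return make_leaf(idx);

    std::vector<int> lidx, ridx;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
    if (lidx.empty() || ridx.empty()) return make_leaf(idx);

    const int node = static_cast<int>(tree.feature.size());
    tree.feature.push_back(best_f);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(0.0);
    tree.left[node] = grow(lidx, depth + 1);
    tree.right[node] = grow(ridx, depth + 1);
    return node;
  }
};

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_node, int max_depth, bool bootstrap, double seed) {
  const int n = X.nrow();
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    const uint64_t tree_seed =
        static_cast<uint64_t>(seed) * 0x100000001B3ULL + static_cast<uint64_t>(t + 1);
    Builder b(X, y, mtry, min_node, max_depth, tree_seed);
    std::vector<int> idx(n);
    if (bootstrap) {
      Rng boot(tree_seed ^ 0xDEADBEEFCAFEULL);
      for (int i = 0; i < n; ++i) idx[i] = boot.below(n);
      std::sort(idx.begin(), idx.end());
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    b.grow(idx, 0);
    forest[t] = List::create(_["feature"] = wrap(b.tree.feature),
                             _["threshold"] = wrap(b.tree.threshold),
                             _["left"] = wrap(b.tree.left),
                             _["right"] = wrap(b.tree.right),
                             _["value"] = wrap(b.tree.value));
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericMatrix out(n, T);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      out(i, t) = value[node];
    }
  }
  return out;
}
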
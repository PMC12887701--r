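// Compact CART-style regression trees used as the base learner for the
// random-forest, extremely-randomized-trees and gradient-boosting models in
// the pathway ML suite. Trees minimize within-node sum of squares; on 0/1
// labels the leaf mean is a class-1 probability. All randomness comes from
// R's RNG, so set.seed() on the R side fixes fits exactly.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  double value;     // node mean of y
};

struct Tree {
  std::vector<Node> nodes;
};

// sample `k` distinct indices from 0..n-1 (partial Fisher-Yates, R RNG)
static void sample_features(int n, int k, std::vector<int> &out) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

struct SplitResult {
  bool ok = false;
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0; // SSE reduction
};

// best split over candidate features; random_split = extra-trees style
// (one uniform threshold per feature instead of an exhaustive scan)
static SplitResult find_split(const NumericMatrix &X, const NumericVector &y,
                              const std::vector<int> &idx, int mtry,
                              int min_node, bool random_split) {
  const int n = (int)idx.size();
  double sum = 0.0;
  for (int i : idx) sum += y[i];
  const double base = sum * sum / n;

  std::vector<int> feats;
  sample_features(X.ncol(), std::min<int>(mtry, X.ncol()), feats);

  SplitResult best;
  std::vector<std::pair<double, double>> vals(n);
  for (int f : feats) {
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue; // constant

    if (random_split) {
      double lo = vals.front().first, hi = vals.back().first;
      double thr = lo + unif_rand() * (hi - lo);
      int nl = 0; double sl = 0.0;
      for (int i = 0; i < n; ++i)
        if (vals[i].first <= thr) { ++nl; sl += vals[i].second; }
      int nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double sr = sum - sl;
      double gain = sl * sl / nl + sr * sr / nr - base;
      if (gain > best.gain) {
        best.ok = true; best.feature = f; best.threshold = thr;
        best.gain = gain;
      }
    } else {
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - base;
        if (gain > best.gain) {
          best.ok = true; best.feature = f;
          best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
          best.gain = gain;
        }
      }
    }
  }
  return best;
}

static int grow(Tree &tree, const NumericMatrix &X, const NumericVector &y,
                const std::vector<int> &idx, int depth, int max_depth,
                int mtry, int min_node, bool random_split,
                std::vector<double> &importance) {
  Node node;
  double sum = 0.0;
  for (int i : idx) sum += y[i];
  node.value = sum / idx.size();
  node.feature = -1;
  node.threshold = 0.0;
  node.left = node.right = -1;
  int me = (int)tree.nodes.size();
  tree.nodes.push_back(node);

  if (depth >= max_depth || (int)idx.size() < 2 * min_node) return me;
  SplitResult s = find_split(X, y, idx, mtry, min_node, random_split);
  if (!s.ok || s.gain <= 1e-12) return me;

  std::vector<int> li, ri;
  for (int i : idx)
    (X(i, s.feature) <= s.threshold ? li : ri).push_back(i);
  if ((int)li.size() < min_node || (int)ri.size() < min_node) return me;

  importance[s.feature] += s.gain;
  tree.nodes[me].feature = s.feature;
  tree.nodes[me].threshold = s.threshold;
  tree.nodes[me].left = grow(tree, X, y, li, depth + 1, max_depth, mtry,
                             min_node, random_split, importance);
  tree.nodes[me].right = grow(tree, X, y, ri, depth + 1, max_depth, mtry,
                              min_node, random_split, importance);
  return me;
}

static NumericMatrix pack(const Tree &tree) {
  NumericMatrix m((int)tree.nodes.size(), 5);
  for (size_t i = 0; i < tree.nodes.size(); ++i) {
    m(i, 0) = tree.nodes[i].feature;
    m(i, 1) = tree.nodes[i].threshold;
    m(i, 2) = tree.nodes[i].left;
    m(i, 3) = tree.nodes[i].right;
    m(i, 4) = tree.nodes[i].value;
  }
  return m;
}

static double predict_one(const NumericMatrix &tree, const NumericMatrix &X,
                          int row) {
  int at = 0;
  while ((int)tree(at, 0) >= 0) {
    int f = (int)tree(at, 0);
    at = (X(row, f) <= tree(at, 1)) ? (int)tree(at, 2) : (int)tree(at, 3);
  }
  return tree(at, 4);
}

} // namespace

// [[Rcpp::export(name = ".fit_forest_cpp")]]
List fit_forest_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int max_depth, int min_node, bool bootstrap,
                    bool random_split) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  std::vector<int> idx;
  for (int t = 0; t < ntree; ++t) {
    idx.clear();
    if (bootstrap) {
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        if (j >= n) j = n - 1;
        idx.push_back(j);
      }
    } else {
      for (int i = 0; i < n; ++i) idx.push_back(i);
    }
    Tree tree;
    grow(tree, X, y, idx, 0, max_depth, mtry, min_node, random_split,
         importance);
    trees[t] = pack(tree);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export(name = ".fit_gbm_cpp")]]
List fit_gbm_cpp(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                 double learning_rate, int min_node, double subsample) {
  const int n = X.nrow(), p = X.ncol();
  double ybar = Rcpp::mean(y);
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double init = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, init), importance(p, 0.0);
  NumericVector resid(n);
  List trees(nrounds);
  std::vector<int> idx;
  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-F[i]));
      resid[i] = y[i] - pr;
    }
    idx.clear();
    for (int i = 0; i < n; ++i)
      if (subsample >= 1.0 || unif_rand() < subsample) idx.push_back(i);
    if ((int)idx.size() < 2 * min_node)
      for (int i = 0; i < n; ++i) idx.push_back(i);
    Tree tree;
    grow(tree, X, resid, idx, 0, max_depth, p, min_node, false, importance);
    NumericMatrix packed = pack(tree);
    for (int i = 0; i < n; ++i)
      F[i] += learning_rate * predict_one(packed, X, i);
    trees[t] = packed;
  }
  return List::create(_["trees"] = trees, _["init"] = init,
                      _["learning_rate"] = learning_rate,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".predict_gbm_cpp")]]
NumericVector predict_gbm_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  double init = model["init"], lr = model["learning_rate"];
  const int n = X.nrow();
  NumericVector F(n, init);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) F[i] += lr * predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) F[i] = 1.0 / (1.0 + std::exp(-F[i]));
  return F;
}
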
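// Random-forest binary classifier with out-of-bag permutation importance.
//
// Only what the codon-importance analysis needs: Gini-grown CART trees on
// continuous features, bootstrap resampling, and for each feature the mean
// decrease in OOB accuracy when that feature's OOB values are permuted.
// A dedicated std::mt19937 stream (seeded per tree from the caller's seed)
// keeps results reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<int> pred;         // leaf class (0/1)
};

static int grow_node(Tree &tree, const NumericMatrix &X,
                     const IntegerVector &y, std::vector<int> &idx,
                     int lo, int hi, int mtry, int min_node,
                     std::mt19937 &rng, std::vector<int> &feat_pool,
                     std::vector<bool> &used_features) {
  int node = tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(0);

  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  tree.pred[node] = (2 * n1 >= n) ? 1 : 0;
  if (n1 == 0 || n1 == n || n < 2 * min_node) return node;

  const double parent_gini =
      1.0 - std::pow((double)n1 / n, 2) - std::pow((double)(n - n1) / n, 2);
  if (parent_gini <= 0.0) return node;

  // sample mtry candidate features without replacement
  int p = X.ncol();
  for (int j = p - 1; j > 0; --j) {
    std::uniform_int_distribution<int> d(0, j);
    std::swap(feat_pool[j], feat_pool[d(rng)]);
  }

  int best_feat = -1;
  double best_score = 0.0, best_thr = 0.0;
  std::vector<std::pair<double, int>> vals;
  vals.reserve(n);
  for (int m = 0; m < mtry; ++m) {
    int j = feat_pool[m];
    vals.clear();
    for (int i = lo; i < hi; ++i)
      vals.emplace_back(X(idx[i], j), y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int left1 = 0;
    for (int k = 0; k < n - 1; ++k) {
      left1 += vals[k].second;
      if (vals[k].first == vals[k + 1].first) continue;
      int nl = k + 1, nr = n - nl;
      int l1 = left1, r1 = n1 - left1;
      double gl = 1.0 - std::pow((double)l1 / nl, 2) -
                  std::pow((double)(nl - l1) / nl, 2);
      double gr = 1.0 - std::pow((double)r1 / nr, 2) -
                  std::pow((double)(nr - r1) / nr, 2);
      double score = parent_gini - ((double)nl / n) * gl -
                     ((double)nr / n) * gr;
      if (score > best_score + 1e-12) {
        best_score = score;
        best_feat = j;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node; // numerical guard

  tree.feature[node] = best_feat;
  tree.threshold[node] = best_thr;
  used_features[best_feat] = true;
  int l = grow_node(tree, X, y, idx, lo, mid, mtry, min_node, rng,
                    feat_pool, used_features);
  int r = grow_node(tree, X, y, idx, mid, hi, mtry, min_node, rng,
                    feat_pool, used_features);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

static int predict_one(const Tree &tree, const NumericMatrix &X, int row,
                       int swap_feat, double swap_val) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    int j = tree.feature[node];
    double v = (j == swap_feat) ? swap_val : X(row, j);
    node = (v <= tree.threshold[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.pred[node];
}

// [[Rcpp::export(name = ".rf_importance_cpp")]]
List rf_importance_cpp(NumericMatrix X, IntegerVector y, int n_trees,
                       int mtry, int min_node, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("label/feature size mismatch");
  std::vector<double> imp(p, 0.0);
  std::vector<int> imp_trees(p, 0);
  double oob_err_sum = 0.0;
  int oob_trees = 0;

  std::vector<int> idx(n), boot(n);
  std::vector<bool> inbag(n);
  std::vector<int> feat_pool(p);
  std::vector<bool> used(p);
  std::vector<int> oob;
  std::vector<int> perm;

  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng(static_cast<uint32_t>(seed) + 0x9e3779b9u * (t + 1));
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::fill(inbag.begin(), inbag.end(), false);
    for (int i = 0; i < n; ++i) {
      boot[i] = pick(rng);
      inbag[boot[i]] = true;
    }
    std::iota(feat_pool.begin(), feat_pool.end(), 0);
    std::fill(used.begin(), used.end(), false);
    Tree tree;
    std::vector<int> node_idx(boot);
    grow_node(tree, X, y, node_idx, 0, n, mtry, min_node, rng, feat_pool,
              used);

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int correct = 0;
    for (int i : oob)
      if (predict_one(tree, X, i, -1, 0.0) == y[i]) ++correct;
    double acc = (double)correct / oob.size();
    oob_err_sum += 1.0 - acc;
    ++oob_trees;

    perm.resize(oob.size());
    for (int j = 0; j < p; ++j) {
      if (!used[j]) { ++imp_trees[j]; continue; } // permuting unused: diff 0
      // permutation of the OOB values of feature j
      std::iota(perm.begin(), perm.end(), 0);
      for (size_t k = perm.size() - 1; k > 0; --k) {
        std::uniform_int_distribution<size_t> d(0, k);
        std::swap(perm[k], perm[d(rng)]);
      }
      int correct_p = 0;
      for (size_t k = 0; k < oob.size(); ++k) {
        double v = X(oob[perm[k]], j);
        if (predict_one(tree, X, oob[k], j, v) == y[oob[k]]) ++correct_p;
      }
      imp[j] += acc - (double)correct_p / oob.size();
      ++imp_trees[j];
    }
  }

  NumericVector importance(p);
  for (int j = 0; j < p; ++j)
    importance[j] = imp_trees[j] > 0 ? imp[j] / imp_trees[j] : 0.0;
  return List::create(
      _["importance"] = importance,
      _["oob_error"] = oob_trees > 0 ? oob_err_sum / oob_trees : NA_REAL);
}
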
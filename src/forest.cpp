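// CART-style random forest for binary classification with Gini
// impurity-decrease importances. Uses R's RNG (unif_rand) so results are
// reproducible under set.seed() from R. Ties in split search are broken
// by lower feature index, then lower threshold, for determinism.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1 => leaf
  double threshold = 0.0; // go left if x <= threshold
  int left = -1, right = -1;
  double pred = 0.0;      // P(y = 1) in the node
};

struct Tree {
  std::vector<Node> nodes;
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

int sample_int(int n) { // uniform on 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Split {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0; // weighted impurity decrease (node-size weighted)
};

Split best_split(const NumericMatrix& X, const IntegerVector& y,
                 const std::vector<int>& idx, const std::vector<int>& feats,
                 int min_node) {
  Split best;
  const int n = (int)idx.size();
  double n1 = 0.0;
  for (int i : idx) n1 += y[i];
  const double imp = gini(n1, n);
  if (imp <= 0.0) return best;
  std::vector<std::pair<double, int>> v(n);
  for (int f : feats) {
    for (int j = 0; j < n; ++j) v[j] = {X(idx[j], f), y[idx[j]]};
    std::sort(v.begin(), v.end());
    double l1 = 0.0;
    for (int j = 0; j < n - 1; ++j) {
      l1 += v[j].second;
      if (v[j].first == v[j + 1].first) continue;
      const double nl = j + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double gain =
          imp - (nl / n) * gini(l1, nl) - (nr / n) * gini(n1 - l1, nr);
      const double thr = v[j].first + 0.5 * (v[j + 1].first - v[j].first);
      if (gain > best.gain + 1e-12 ||
          (std::abs(gain - best.gain) <= 1e-12 && best.feature >= 0 &&
           (f < best.feature ||
            (f == best.feature && thr < best.threshold)))) {
        best.feature = f;
        best.threshold = thr;
        best.gain = gain;
      }
    }
  }
  return best;
}

void grow(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
          std::vector<int>& idx, int depth, int max_depth, int mtry,
          int min_node, std::vector<double>& imp, double n_total, int node_id) {
  const int n = (int)idx.size();
  const int p = X.ncol();
  double n1 = 0.0;
  for (int i : idx) n1 += y[i];
  tree.nodes[node_id].pred = n > 0 ? n1 / n : 0.5;

  bool stop = depth >= max_depth || n < 2 * min_node || n1 == 0.0 ||
              n1 == (double)n;
  Split sp;
  if (!stop) {
    // draw mtry distinct features (partial Fisher-Yates on 0..p-1)
    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    std::vector<int> feats(mtry);
    for (int j = 0; j < mtry; ++j) {
      int k = j + sample_int(p - j);
      std::swap(pool[j], pool[k]);
      feats[j] = pool[j];
    }
    std::sort(feats.begin(), feats.end());
    sp = best_split(X, y, idx, feats, min_node);
    if (sp.feature < 0) stop = true;
  }
  if (stop) return; // leaf: feature stays -1

  imp[sp.feature] += ((double)n / n_total) * sp.gain;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int i : idx) {
    if (X(i, sp.feature) <= sp.threshold)
      left_idx.push_back(i);
    else
      right_idx.push_back(i);
  }
  tree.nodes[node_id].feature = sp.feature;
  tree.nodes[node_id].threshold = sp.threshold;
  const int li = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  const int ri = (int)tree.nodes.size();
  tree.nodes.push_back(Node());
  tree.nodes[node_id].left = li;
  tree.nodes[node_id].right = ri;
  grow(tree, X, y, left_idx, depth + 1, max_depth, mtry, min_node, imp,
       n_total, li);
  grow(tree, X, y, right_idx, depth + 1, max_depth, mtry, min_node, imp,
       n_total, ri);
}

double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    cur = X(row, tree.nodes[cur].feature) <= tree.nodes[cur].threshold
              ? tree.nodes[cur].left
              : tree.nodes[cur].right;
  }
  return tree.nodes[cur].pred;
}

} // namespace

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
             int mtry, int min_node, bool bootstrap) {
  RNGScope scope;
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  std::vector<double> imp(p, 0.0);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = sample_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    Tree tree;
    tree.nodes.push_back(Node());
    grow(tree, X, y, idx, 0, max_depth, mtry, min_node, imp, (double)n, 0);
    const int m = (int)tree.nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), pred(m);
    for (int j = 0; j < m; ++j) {
      feature[j] = tree.nodes[j].feature;
      threshold[j] = tree.nodes[j].threshold;
      left[j] = tree.nodes[j].left;
      right[j] = tree.nodes[j].right;
      pred[j] = tree.nodes[j].pred;
    }
    trees[t] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right,
                            _["pred"] = pred);
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / n_trees;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    Tree tree;
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector threshold = tr["threshold"], pred = tr["pred"];
    const int m = feature.size();
    tree.nodes.resize(m);
    for (int j = 0; j < m; ++j) {
      tree.nodes[j].feature = feature[j];
      tree.nodes[j].threshold = threshold[j];
      tree.nodes[j].left = left[j];
      tree.nodes[j].right = right[j];
      tree.nodes[j].pred = pred[j];
    }
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tree, X, i);
  }
  return out / (double)T;
}

// [[Rcpp::export(name = ".rf_max_path_depth")]]
int rf_max_path_depth(List tr) {
  IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
  const int m = feature.size();
  std::vector<int> depth(m, 0);
  int best = 0;
  for (int j = 0; j < m; ++j) {
    if (feature[j] >= 0) {
      depth[left[j]] = depth[j] + 1;
      depth[right[j]] = depth[j] + 1;
      best = std::max(best, depth[j] + 1);
    }
  }
  return best;
}
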
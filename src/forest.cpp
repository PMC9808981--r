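// Bagged CART classification forest (Gini splits).
//
// All randomness (bootstrap resampling, per-split feature
// subsampling) is drawn from R's RNG stream, so results are fully
// reproducible under set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<int> leaf_class;
};

int rint(int n) {  // uniform integer in [0, n)
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

int majority(const std::vector<int>& counts) {
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k)
    if (counts[k] > counts[best]) best = static_cast<int>(k);
  return best;
}

// best Gini split of `idx` on feature j; returns impurity decrease
// (negative if none) and writes threshold
double best_split_feature(const NumericMatrix& X,
                          const IntegerVector& y, int n_classes,
                          const std::vector<int>& idx, int j,
                          double parent_gini, double& thr_out) {
  size_t n = idx.size();
  std::vector<std::pair<double, int> > v(n);
  for (size_t i = 0; i < n; ++i)
    v[i] = std::make_pair(X(idx[i], j), y[idx[i]]);
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return -1.0;
  std::vector<int> left_c(n_classes, 0), right_c(n_classes, 0);
  for (size_t i = 0; i < n; ++i) right_c[v[i].second]++;
  double best = -1.0;
  int n_left = 0, n_right = static_cast<int>(n);
  for (size_t i = 0; i + 1 < n; ++i) {
    left_c[v[i].second]++; right_c[v[i].second]--;
    n_left++; n_right--;
    if (v[i].first == v[i + 1].first) continue;
    double gl = 1.0, gr = 1.0;
    for (int k = 0; k < n_classes; ++k) {
      double pl = static_cast<double>(left_c[k]) / n_left;
      double pr = static_cast<double>(right_c[k]) / n_right;
      gl -= pl * pl; gr -= pr * pr;
    }
    double dec = parent_gini -
      (n_left * gl + n_right * gr) / static_cast<double>(n);
    if (dec > best + 1e-15) {
      best = dec;
      thr_out = 0.5 * (v[i].first + v[i + 1].first);
    }
  }
  return best;
}

void grow(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
          int n_classes, std::vector<int>& idx, int mtry,
          int min_node, int node) {
  std::vector<int> counts(n_classes, 0);
  for (size_t i = 0; i < idx.size(); ++i) counts[y[idx[i]]]++;
  int nz = 0;
  for (int k = 0; k < n_classes; ++k) if (counts[k] > 0) nz++;
  bool make_leaf = (nz <= 1) ||
    (static_cast<int>(idx.size()) < min_node);
  int p = X.ncol();
  int best_j = -1;
  double best_dec = 0.0, best_thr = 0.0;
  if (!make_leaf) {
    double gini = 1.0;
    for (int k = 0; k < n_classes; ++k) {
      double pk = static_cast<double>(counts[k]) / idx.size();
      gini -= pk * pk;
    }
    // sample mtry features without replacement (partial shuffle)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j)
      std::swap(feats[j], feats[j + rint(p - j)]);
    for (int j = 0; j < m; ++j) {
      double thr;
      double dec = best_split_feature(X, y, n_classes, idx, feats[j],
                                      gini, thr);
      if (dec > best_dec + 1e-15) {
        best_dec = dec; best_thr = thr; best_j = feats[j];
      }
    }
    if (best_j < 0) make_leaf = true;
  }
  if (make_leaf) {
    tree.feature[node] = -1;
    tree.leaf_class[node] = majority(counts);
    return;
  }
  std::vector<int> li, ri;
  for (size_t i = 0; i < idx.size(); ++i) {
    if (X(idx[i], best_j) <= best_thr) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  tree.feature[node] = best_j;
  tree.thr[node] = best_thr;
  int ln = static_cast<int>(tree.feature.size());
  tree.feature.push_back(0); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.leaf_class.push_back(-1);
  tree.feature.push_back(0); tree.thr.push_back(0.0);
  tree.left.push_back(-1); tree.right.push_back(-1);
  tree.leaf_class.push_back(-1);
  tree.left[node] = ln;
  tree.right[node] = ln + 1;
  grow(tree, X, y, n_classes, li, mtry, min_node, ln);
  grow(tree, X, y, n_classes, ri, mtry, min_node, ln + 1);
}

int predict_one(const Tree& tree, const NumericMatrix& X, int i) {
  int node = 0;
  while (tree.feature[node] >= 0)
    node = (X(i, tree.feature[node]) <= tree.thr[node]) ?
      tree.left[node] : tree.right[node];
  return tree.leaf_class[node];
}

List pack_tree(const Tree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left),
                      _["right"] = wrap(t.right),
                      _["leaf_class"] = wrap(t.leaf_class));
}

Tree unpack_tree(const List& l) {
  Tree t;
  t.feature = as<std::vector<int> >(l["feature"]);
  t.thr = as<std::vector<double> >(l["thr"]);
  t.left = as<std::vector<int> >(l["left"]);
  t.right = as<std::vector<int> >(l["right"]);
  t.leaf_class = as<std::vector<int> >(l["leaf_class"]);
  return t;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                int n_trees, int mtry, int min_node) {
  int n = X.nrow();
  List trees(n_trees);
  IntegerMatrix oob_votes(n, n_classes);
  std::vector<char> inbag(n);
  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = rint(n);
      inbag[idx[i]] = 1;
    }
    Tree tree;
    tree.feature.assign(1, 0); tree.thr.assign(1, 0.0);
    tree.left.assign(1, -1); tree.right.assign(1, -1);
    tree.leaf_class.assign(1, -1);
    grow(tree, X, y, n_classes, idx, mtry, min_node, 0);
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob_votes(i, predict_one(tree, X, i))++;
    trees[t] = pack_tree(tree);
  }
  return List::create(_["trees"] = trees,
                      _["oob_votes"] = oob_votes,
                      _["n_classes"] = n_classes);
}

// [[Rcpp::export(name = ".rf_votes_cpp")]]
IntegerMatrix rf_votes_cpp(List model, NumericMatrix X) {
  List trees = model["trees"];
  int n_classes = as<int>(model["n_classes"]);
  int n = X.nrow(), T = trees.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < T; ++t) {
    Tree tree = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i)
      votes(i, predict_one(tree, X, i))++;
  }
  return votes;
}
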
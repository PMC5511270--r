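#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Tree node matrix layout (one row per node, indices 1-based, 0 = none):
//   col 0: feature (1-based; 0 marks a leaf)
//   col 1: split threshold (go left when x <= threshold)
//   col 2: terminal value on the log-odds scale (NA for internal nodes)
//   col 3: left child row
//   col 4: right child row
//   col 5: squared-error improvement achieved by the split (0 for leaves)

struct Node {
  int feature;        // 0 = leaf
  double threshold;
  double value;
  int left, right;    // 0 = none
  double improvement;
};

// Best split of `rows` on the residual vector r. Exhaustive over midpoints
// of sorted unique values; ties broken by lowest feature index then lowest
// threshold (features and thresholds scanned ascending, strict > to update).
static void best_split(const NumericMatrix& X, const std::vector<double>& r,
                       const std::vector<int>& rows, int min_node,
                       int& bf, double& bthr, double& bimp) {
  const int n = (int)rows.size(), p = X.ncol();
  bf = -1; bthr = 0.0; bimp = 0.0;
  double sum = 0.0;
  for (int i = 0; i < n; ++i) sum += r[rows[i]];
  const double base = sum * sum / n;
  std::vector<std::pair<double,double> > v(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i)
      v[i] = std::make_pair(X(rows[i], f), r[rows[i]]);
    std::sort(v.begin(), v.end());
    double cum = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      cum += v[i].second;
      if (v[i].first == v[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double sl = cum, sr = sum - cum;
      const double imp = sl * sl / nl + sr * sr / nr - base;
      if (imp > bimp) {
        bimp = imp; bf = f; bthr = (v[i].first + v[i + 1].first) / 2.0;
      }
    }
  }
}

// Grow a node; returns its index in `nodes`. level is 1 at the root; a node
// may split while level <= max_depth.
static int grow(std::vector<Node>& nodes, const NumericMatrix& X,
                const std::vector<double>& r, const std::vector<double>& w,
                const std::vector<int>& rows, int level, int max_depth,
                int min_node) {
  int bf = -1; double bthr = 0.0, bimp = 0.0;
  if (level <= max_depth && (int)rows.size() >= 2 * min_node)
    best_split(X, r, rows, min_node, bf, bthr, bimp);
  Node nd;
  if (bf < 0) {
    double sr = 0.0, sw = 0.0;
    for (size_t i = 0; i < rows.size(); ++i) { sr += r[rows[i]]; sw += w[rows[i]]; }
    nd.feature = 0; nd.threshold = 0.0; nd.left = nd.right = 0;
    nd.improvement = 0.0;
    nd.value = sr / std::max(sw, 1e-12);  // one-step Newton estimate
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }
  nd.feature = bf + 1; nd.threshold = bthr; nd.value = NA_REAL;
  nd.left = nd.right = 0; nd.improvement = bimp;
  nodes.push_back(nd);
  const int me = (int)nodes.size() - 1;
  std::vector<int> lrows, rrows;
  for (size_t i = 0; i < rows.size(); ++i) {
    if (X(rows[i], bf) <= bthr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  const int li = grow(nodes, X, r, w, lrows, level + 1, max_depth, min_node);
  nodes[me].left = li + 1;
  const int ri = grow(nodes, X, r, w, rrows, level + 1, max_depth, min_node);
  nodes[me].right = ri + 1;
  return me;
}

static NumericMatrix pack(const std::vector<Node>& nodes) {
  NumericMatrix T((int)nodes.size(), 6);
  for (size_t i = 0; i < nodes.size(); ++i) {
    T(i, 0) = nodes[i].feature;
    T(i, 1) = nodes[i].threshold;
    T(i, 2) = nodes[i].value;
    T(i, 3) = nodes[i].left;
    T(i, 4) = nodes[i].right;
    T(i, 5) = nodes[i].improvement;
  }
  return T;
}

static double tree_value(const NumericMatrix& T, const NumericMatrix& X, int i) {
  int node = 0;
  while ((int)T(node, 0) != 0) {
    const int f = (int)T(node, 0) - 1;
    node = (X(i, f) <= T(node, 1)) ? (int)T(node, 3) - 1 : (int)T(node, 4) - 1;
  }
  return T(node, 2);
}

// As tree_value but with the features in `cols` (0-based) overridden by `g`.
static double tree_value_override(const NumericMatrix& T, const NumericMatrix& X,
                                  int i, const std::vector<int>& cols,
                                  const std::vector<double>& g) {
  int node = 0;
  while ((int)T(node, 0) != 0) {
    const int f = (int)T(node, 0) - 1;
    double x = X(i, f);
    for (size_t c = 0; c < cols.size(); ++c)
      if (cols[c] == f) { x = g[c]; break; }
    node = (x <= T(node, 1)) ? (int)T(node, 3) - 1 : (int)T(node, 4) - 1;
  }
  return T(node, 2);
}

// [[Rcpp::export]]
List fit_gbt_cpp(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                 double shrinkage, int min_node, double bag_fraction) {
  const int n = X.nrow();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  const double F0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, F0), prob(n), r(n), w(n);
  List trees(n_trees);
  const bool bag = bag_fraction < 1.0;
  int n_bag = bag ? (int)std::floor(bag_fraction * n) : n;
  if (n_bag < 1) n_bag = 1;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  for (int m = 0; m < n_trees; ++m) {
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - prob[i];
      w[i] = prob[i] * (1.0 - prob[i]);
    }
    std::vector<int> rows;
    if (bag) {
      // draws from R's RNG stream: deterministic under set.seed()
      IntegerVector s = Rcpp::sample(n, n_bag, false);
      rows.resize(n_bag);
      for (int i = 0; i < n_bag; ++i) rows[i] = s[i] - 1;
      std::sort(rows.begin(), rows.end());
    } else {
      rows = all;
    }
    std::vector<Node> nodes;
    grow(nodes, X, r, w, rows, 1, max_depth, min_node);
    NumericMatrix T = pack(nodes);
    trees[m] = T;
    for (int i = 0; i < n; ++i) F[i] += shrinkage * tree_value(T, X, i);
  }
  return List::create(_["intercept"] = F0, _["trees"] = trees);
}

// [[Rcpp::export]]
NumericVector predict_margin_cpp(List trees, double intercept, double shrinkage,
                                 NumericMatrix X) {
  const int n = X.nrow(), M = trees.size();
  NumericVector out(n, intercept);
  for (int m = 0; m < M; ++m) {
    NumericMatrix T = trees[m];
    for (int i = 0; i < n; ++i) out[i] += shrinkage * tree_value(T, X, i);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix staged_margin_cpp(List trees, double intercept, double shrinkage,
                                NumericMatrix X) {
  const int n = X.nrow(), M = trees.size();
  NumericMatrix out(n, M + 1);
  for (int i = 0; i < n; ++i) out(i, 0) = intercept;
  for (int m = 0; m < M; ++m) {
    NumericMatrix T = trees[m];
    for (int i = 0; i < n; ++i)
      out(i, m + 1) = out(i, m) + shrinkage * tree_value(T, X, i);
  }
  return out;
}

// Partial dependence on the margin scale: for each grid row, the mean over
// data rows of the ensemble margin with the target columns overridden.
// [[Rcpp::export]]
NumericVector pd_margin_cpp(List trees, double intercept, double shrinkage,
                            NumericMatrix X, IntegerVector cols,
                            NumericMatrix grid) {
  const int n = X.nrow(), M = trees.size(), G = grid.nrow();
  std::vector<int> cc(cols.size());
  for (int c = 0; c < cols.size(); ++c) cc[c] = cols[c] - 1;
  NumericVector out(G);
  std::vector<double> g(cols.size());
  for (int gi = 0; gi < G; ++gi) {
    for (int c = 0; c < (int)cc.size(); ++c) g[c] = grid(gi, c);
    double acc = 0.0;
    for (int m = 0; m < M; ++m) {
      NumericMatrix T = trees[m];
      for (int i = 0; i < n; ++i)
        acc += tree_value_override(T, X, i, cc, g);
    }
    out[gi] = intercept + shrinkage * acc / n;
  }
  return out;
}
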
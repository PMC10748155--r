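// CART-style tree ensembles used as stacking meta-learners: a random forest
// (gini splits, bootstrap + feature subsampling, mean-impurity-decrease
// importances) and gradient-boosted regression trees on the logistic loss
// (second-order leaf weights, total-gain importances).
//
// Feature dimensionality here is tiny (2-6 stacked probabilities), so exact
// greedy split search over all thresholds is used throughout. All randomness
// comes from R's RNG stream, so set.seed() on the R side fixes the fit.
//
// Trees are returned as numeric node tables with columns
// (feature, threshold, left, right, value); feature < 0 marks a leaf and
// `value` holds the leaf prediction. Indices are 0-based, x <= threshold
// goes left.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

struct Node {
  int feat = -1;
  double thr = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

static int rand_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static std::vector<int> sample_features(int d, int mtry) {
  std::vector<int> f(d);
  for (int i = 0; i < d; ++i) f[i] = i;
  for (int i = 0; i < mtry; ++i) {
    int j = i + rand_int(d - i);
    std::swap(f[i], f[j]);
  }
  f.resize(mtry);
  std::sort(f.begin(), f.end()); // deterministic evaluation order
  return f;
}

// ---------------------------------------------------------------- forest ---

static double gini(double pos, double n) {
  if (n <= 0) return 0.0;
  double p = pos / n;
  return 2.0 * p * (1.0 - p);
}

static int grow_gini(const NumericMatrix& X, const IntegerVector& y,
                     std::vector<int>& idx, int lo, int hi, int depth,
                     int max_depth, int min_split, int mtry,
                     double n_total, std::vector<Node>& nodes,
                     std::vector<double>& imp) {
  const int n = hi - lo;
  double pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  Node nd;
  nd.value = pos / n;
  const double g_parent = gini(pos, n);
  bool stop = n < min_split || g_parent <= 0.0 ||
              (max_depth > 0 && depth >= max_depth);
  if (!stop) {
    const int d = X.ncol();
    std::vector<int> feats = sample_features(d, std::min(mtry, d));
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    for (int f : feats) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double pl = 0;
      for (int i = 0; i < n - 1; ++i) {
        pl += y[ord[i]];
        if (X(ord[i + 1], f) <= X(ord[i], f)) continue; // tie: no cut here
        const double nl = i + 1, nr = n - nl;
        const double gain =
            g_parent - (nl / n) * gini(pl, nl) - (nr / n) * gini(pos - pl, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        }
      }
    }
    if (best_f >= 0) {
      imp[best_f] += (n / n_total) * best_gain;
      int mid = lo;
      for (int i = lo; i < hi; ++i)
        if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
      nd.feat = best_f;
      nd.thr = best_thr;
      int self = (int)nodes.size();
      nodes.push_back(nd);
      int l = grow_gini(X, y, idx, lo, mid, depth + 1, max_depth, min_split,
                        mtry, n_total, nodes, imp);
      int r = grow_gini(X, y, idx, mid, hi, depth + 1, max_depth, min_split,
                        mtry, n_total, nodes, imp);
      nodes[self].left = l;
      nodes[self].right = r;
      return self;
    }
  }
  nodes.push_back(nd);
  return (int)nodes.size() - 1;
}

static NumericMatrix pack_nodes(const std::vector<Node>& nodes) {
  NumericMatrix m(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feat;
    m(i, 1) = nodes[i].thr;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

// [[Rcpp::export]]
List forest_fit(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
                int mtry, int min_split) {
  const int n = X.nrow(), d = X.ncol();
  List trees(n_trees);
  std::vector<double> imp(d, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n); // bootstrap
    std::vector<Node> nodes;
    std::vector<double> imp_t(d, 0.0);
    grow_gini(X, y, idx, 0, n, 0, max_depth, min_split, mtry, (double)n,
              nodes, imp_t);
    for (int j = 0; j < d; ++j) imp[j] += imp_t[j] / n_trees;
    trees[t] = pack_nodes(nodes);
  }
  return List::create(Named("trees") = trees,
                      Named("importance") = NumericVector(imp.begin(), imp.end()));
}

static double tree_eval(const NumericMatrix& nd, const NumericMatrix& X, int i) {
  int cur = 0;
  while (nd(cur, 0) >= 0)
    cur = (X(i, (int)nd(cur, 0)) <= nd(cur, 1)) ? (int)nd(cur, 2)
                                                : (int)nd(cur, 3);
  return nd(cur, 4);
}

// [[Rcpp::export]]
NumericVector forest_predict_prob(List model, NumericMatrix X) {
  List trees = model["trees"];
  const int n = X.nrow(), T = trees.size();
  NumericVector p(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nd = trees[t];
    for (int i = 0; i < n; ++i) p[i] += tree_eval(nd, X, i);
  }
  for (int i = 0; i < n; ++i) p[i] /= T;
  return p;
}

// --------------------------------------------------------------- boosting ---

static int grow_grad(const NumericMatrix& X, const std::vector<double>& g,
                     const std::vector<double>& h, std::vector<int>& idx,
                     int lo, int hi, int depth, int max_depth, double lambda,
                     double min_child_weight, std::vector<Node>& nodes,
                     std::vector<double>& gain_imp) {
  const int n = hi - lo;
  double G = 0, H = 0;
  for (int i = lo; i < hi; ++i) { G += g[idx[i]]; H += h[idx[i]]; }
  Node nd;
  nd.value = -G / (H + lambda);
  if (n >= 2 && depth < max_depth) {
    const int d = X.ncol();
    const double score_parent = G * G / (H + lambda);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    for (int f = 0; f < d; ++f) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double GL = 0, HL = 0;
      for (int i = 0; i < n - 1; ++i) {
        GL += g[ord[i]]; HL += h[ord[i]];
        if (X(ord[i + 1], f) <= X(ord[i], f)) continue;
        const double GR = G - GL, HR = H - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                   GR * GR / (HR + lambda) - score_parent);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (X(ord[i], f) + X(ord[i + 1], f));
        }
      }
    }
    if (best_f >= 0) {
      gain_imp[best_f] += best_gain;
      int mid = lo;
      for (int i = lo; i < hi; ++i)
        if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
      nd.feat = best_f;
      nd.thr = best_thr;
      int self = (int)nodes.size();
      nodes.push_back(nd);
      int l = grow_grad(X, g, h, idx, lo, mid, depth + 1, max_depth, lambda,
                        min_child_weight, nodes, gain_imp);
      int r = grow_grad(X, g, h, idx, mid, hi, depth + 1, max_depth, lambda,
                        min_child_weight, nodes, gain_imp);
      nodes[self].left = l;
      nodes[self].right = r;
      return self;
    }
  }
  nodes.push_back(nd);
  return (int)nodes.size() - 1;
}

// [[Rcpp::export]]
List gbt_fit(NumericMatrix X, IntegerVector y, int n_rounds, int max_depth,
             double learning_rate, double lambda, double subsample,
             double min_child_weight) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<double> margin(n, 0.0), g(n), h(n);
  List trees(n_rounds);
  std::vector<double> gain_imp(d, 0.0);
  for (int t = 0; t < n_rounds; ++t) {
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) {
      const double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-16);
      if (subsample >= 1.0 || unif_rand() < subsample) idx.push_back(i);
    }
    if (idx.empty()) idx.push_back(rand_int(n));
    std::vector<Node> nodes;
    grow_grad(X, g, h, idx, 0, (int)idx.size(), 0, max_depth, lambda,
              min_child_weight, nodes, gain_imp);
    NumericMatrix nd = pack_nodes(nodes);
    for (int i = 0; i < n; ++i)
      margin[i] += learning_rate * tree_eval(nd, X, i);
    trees[t] = nd;
  }
  return List::create(
      Named("trees") = trees,
      Named("learning_rate") = learning_rate,
      Named("importance") = NumericVector(gain_imp.begin(), gain_imp.end()));
}

// [[Rcpp::export]]
NumericVector gbt_predict_prob(List model, NumericMatrix X) {
  List trees = model["trees"];
  const double lr = as<double>(model["learning_rate"]);
  const int n = X.nrow(), T = trees.size();
  NumericVector m(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nd = trees[t];
    for (int i = 0; i < n; ++i) m[i] += lr * tree_eval(nd, X, i);
  }
  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = 1.0 / (1.0 + std::exp(-m[i]));
  return p;
}
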
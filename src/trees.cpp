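// Regression-tree engine backing the random_forest, extra_trees and
// gradient_boosting families. Split search uses per-fit presorted feature
// orders with stable partitioning down the tree (no per-node sorting).
// Trees are returned to R as plain numeric matrices (one row per node:
// feature, threshold, left, right, value) so fitted models are serializable
// without external pointers.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

typedef std::vector<std::vector<int> > SortedLists;  // one list per pool feat

struct TreeBuilder {
  const std::vector<double>& X;  // column-major n_total x p
  int n_total;
  const std::vector<double>& y;  // per-row targets (residuals for boosting)
  const std::vector<int>& pool;  // candidate feature columns
  int max_depth, min_leaf, mtry;
  bool random_threshold;
  double leaf_lambda;
  std::mt19937& rng;

  std::vector<double> node_feature, node_threshold, node_left, node_right,
      node_value;

  TreeBuilder(const std::vector<double>& X_, int n_total_,
              const std::vector<double>& y_, const std::vector<int>& pool_,
              int max_depth_, int min_leaf_, int mtry_, bool random_thr_,
              double leaf_lambda_, std::mt19937& rng_)
      : X(X_), n_total(n_total_), y(y_), pool(pool_), max_depth(max_depth_),
        min_leaf(min_leaf_), mtry(mtry_), random_threshold(random_thr_),
        leaf_lambda(leaf_lambda_), rng(rng_) {}

  double xval(int row, int f) const { return X[(size_t)f * n_total + row]; }

  int make_leaf(const std::vector<int>& rows) {
    double s = 0.0;
    for (int r : rows) s += y[r];
    int id = (int)node_feature.size();
    node_feature.push_back(-1);
    node_threshold.push_back(0.0);
    node_left.push_back(-1);
    node_right.push_back(-1);
    node_value.push_back(s / (rows.size() + leaf_lambda));
    return id;
  }

  // best-split scan over one feature's presorted row list
  void scan_feature(const std::vector<int>& srt, int f, double s_tot,
                    double& best_gain, double& best_thr, int& best_f) {
    const int n = (int)srt.size();
    if (random_threshold) {
      double lo = xval(srt.front(), f), hi = xval(srt.back(), f);
      if (hi <= lo) return;
      std::uniform_real_distribution<double> U(lo, hi);
      double thr = U(rng);
      double sl = 0.0;
      int nl = 0;
      for (int i = 0; i < n && xval(srt[i], f) <= thr; ++i) {
        sl += y[srt[i]];
        ++nl;
      }
      int nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) return;
      double sr = s_tot - sl;
      double gain = sl * sl / nl + sr * sr / nr - s_tot * s_tot / n;
      if (gain > best_gain) { best_gain = gain; best_thr = thr; best_f = f; }
      return;
    }
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += y[srt[i]];
      double xi = xval(srt[i], f), xn = xval(srt[i + 1], f);
      if (xi >= xn) continue;  // tied values: no cut here
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      double sr = s_tot - sl;
      double gain = sl * sl / nl + sr * sr / nr - s_tot * s_tot / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_thr = 0.5 * (xi + xn);
        best_f = f;
      }
    }
  }

  int build(SortedLists& lists, int depth) {
    const std::vector<int>& rows = lists[0];
    const int n = (int)rows.size();
    if (depth >= max_depth || n < 2 * min_leaf || n < 2)
      return make_leaf(rows);

    // feature subset of size mtry from the pool
    std::vector<int> cand((size_t)pool.size());
    for (size_t i = 0; i < pool.size(); ++i) cand[i] = (int)i;
    int m = std::min<int>(mtry, (int)cand.size());
    for (int i = 0; i < m; ++i) {
      std::uniform_int_distribution<int> U(i, (int)cand.size() - 1);
      std::swap(cand[i], cand[U(rng)]);
    }

    double s_tot = 0.0;
    for (int r : rows) s_tot += y[r];
    double best_gain = 1e-12;  // require strictly positive improvement
    double best_thr = 0.0;
    int best_f = -1, best_slot = -1;
    for (int i = 0; i < m; ++i) {
      int prev = best_f;
      scan_feature(lists[cand[i]], pool[cand[i]], s_tot, best_gain, best_thr,
                   best_f);
      if (best_f != prev) best_slot = cand[i];
    }
    (void)best_slot;
    if (best_f < 0) return make_leaf(rows);

    // stable partition of every feature list by the chosen split
    std::vector<char> goes_left(n_total, 0);
    int nl = 0;
    for (int r : rows)
      if (xval(r, best_f) <= best_thr) { goes_left[r] = 1; ++nl; }
    int nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) return make_leaf(rows);

    SortedLists left((size_t)lists.size()), right((size_t)lists.size());
    for (size_t fl = 0; fl < lists.size(); ++fl) {
      left[fl].reserve(nl);
      right[fl].reserve(nr);
      for (int r : lists[fl])
        (goes_left[r] ? left[fl] : right[fl]).push_back(r);
      std::vector<int>().swap(lists[fl]);  // free as we descend
    }

    int id = (int)node_feature.size();
    node_feature.push_back(best_f);
    node_threshold.push_back(best_thr);
    node_left.push_back(-2);
    node_right.push_back(-2);
    node_value.push_back(0.0);
    int l = build(left, depth + 1);
    int r = build(right, depth + 1);
    node_left[id] = l;
    node_right[id] = r;
    return id;
  }

  NumericMatrix as_matrix() {
    int nn = (int)node_feature.size();
    NumericMatrix M(nn, 5);
    for (int i = 0; i < nn; ++i) {
      M(i, 0) = node_feature[i];
      M(i, 1) = node_threshold[i];
      M(i, 2) = node_left[i];
      M(i, 3) = node_right[i];
      M(i, 4) = node_value[i];
    }
    return M;
  }
};

std::vector<double> to_colmajor(const NumericMatrix& X) {
  return std::vector<double>(X.begin(), X.end());
}

// presort all rows once per fit: order[f] = row ids ascending by X[, f]
std::vector<std::vector<int> > presort(const std::vector<double>& X, int n,
                                       int p) {
  std::vector<std::vector<int> > order((size_t)p);
  for (int f = 0; f < p; ++f) {
    order[f].resize(n);
    for (int i = 0; i < n; ++i) order[f][i] = i;
    const double* col = &X[(size_t)f * n];
    std::stable_sort(order[f].begin(), order[f].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  return order;
}

// root lists for a tree: global presorted orders filtered by row
// multiplicity (bootstrap counts or subsample mask)
SortedLists root_lists(const std::vector<std::vector<int> >& order,
                       const std::vector<int>& pool,
                       const std::vector<int>& cnt) {
  SortedLists lists(pool.size());
  for (size_t fl = 0; fl < pool.size(); ++fl) {
    const std::vector<int>& ord = order[pool[fl]];
    for (int r : ord)
      for (int c = 0; c < cnt[r]; ++c) lists[fl].push_back(r);
  }
  return lists;
}

double predict_row(const double* M, int nn, const double* Xrow_colmaj, int n,
                   int row) {
  int node = 0;
  while (M[node] >= 0) {  // column 0: feature
    int f = (int)M[node];
    double thr = M[nn + node];
    node = (Xrow_colmaj[(size_t)f * n + row] <= thr) ? (int)M[2 * nn + node]
                                                     : (int)M[3 * nn + node];
  }
  return M[4 * nn + node];
}

}  // namespace

// [[Rcpp::export]]
List fg_forest_fit(NumericMatrix Xin, NumericVector yin, int n_trees,
                   int max_depth, int min_leaf, double feature_fraction,
                   bool bootstrap, bool random_threshold, int seed) {
  int n = Xin.nrow(), p = Xin.ncol();
  std::vector<double> X = to_colmajor(Xin);
  std::vector<double> y(yin.begin(), yin.end());
  std::mt19937 rng((unsigned)seed);
  std::vector<std::vector<int> > order = presort(X, n, p);
  std::vector<int> pool(p);
  for (int f = 0; f < p; ++f) pool[f] = f;
  int mtry = std::max(1, (int)std::lround(feature_fraction * p));
  List trees(n_trees);
  std::uniform_int_distribution<int> Un(0, n - 1);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> cnt(n, bootstrap ? 0 : 1);
    if (bootstrap)
      for (int i = 0; i < n; ++i) ++cnt[Un(rng)];
    SortedLists lists = root_lists(order, pool, cnt);
    TreeBuilder tb(X, n, y, pool, max_depth, min_leaf, mtry,
                   random_threshold, 0.0, rng);
    tb.build(lists, 0);
    trees[t] = tb.as_matrix();
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector fg_forest_predict(List trees, NumericMatrix Xin) {
  int n = Xin.nrow(), T = trees.size();
  std::vector<double> X = to_colmajor(Xin);
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = trees[t];
    int nn = M.nrow();
    const double* Mp = M.begin();
    for (int i = 0; i < n; ++i) out[i] += predict_row(Mp, nn, &X[0], n, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// [[Rcpp::export]]
List fg_gbt_fit(NumericMatrix Xin, NumericVector yin, int n_trees,
                double learning_rate, int max_depth, int min_leaf,
                double subsample, double colsample, double lambda, int seed) {
  int n = Xin.nrow(), p = Xin.ncol();
  std::vector<double> X = to_colmajor(Xin);
  std::mt19937 rng((unsigned)seed);
  std::vector<std::vector<int> > order = presort(X, n, p);
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += yin[i];
  init /= n;
  std::vector<double> pred(n, init), resid(n);
  List trees(n_trees);
  int n_sub = std::max(2 * min_leaf, (int)std::lround(subsample * n));
  n_sub = std::min(n_sub, n);
  int p_sub = std::max(1, (int)std::lround(colsample * p));
  std::vector<int> all_rows(n), all_feats(p);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  for (int f = 0; f < p; ++f) all_feats[f] = f;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = yin[i] - pred[i];
    // row subsample without replacement
    std::vector<int> rows(all_rows);
    for (int i = 0; i < n_sub; ++i) {
      std::uniform_int_distribution<int> U(i, n - 1);
      std::swap(rows[i], rows[U(rng)]);
    }
    std::vector<int> cnt(n, 0);
    for (int i = 0; i < n_sub; ++i) cnt[rows[i]] = 1;
    // per-tree feature pool
    std::vector<int> feats(all_feats);
    for (int i = 0; i < p_sub; ++i) {
      std::uniform_int_distribution<int> U(i, p - 1);
      std::swap(feats[i], feats[U(rng)]);
    }
    feats.resize(p_sub);
    std::sort(feats.begin(), feats.end());
    SortedLists lists = root_lists(order, feats, cnt);
    TreeBuilder tb(X, n, resid, feats, max_depth, min_leaf, p_sub, false,
                   lambda, rng);
    tb.build(lists, 0);
    NumericMatrix M = tb.as_matrix();
    int nn = M.nrow();
    const double* Mp = M.begin();
    for (int i = 0; i < n; ++i)
      pred[i] += learning_rate * predict_row(Mp, nn, &X[0], n, i);
    trees[t] = M;
  }
  return List::create(_["init"] = init, _["learning_rate"] = learning_rate,
                      _["trees"] = trees);
}

// [[Rcpp::export]]
NumericVector fg_gbt_predict(List model, NumericMatrix Xin) {
  double init = as<double>(model["init"]);
  double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  int n = Xin.nrow(), T = trees.size();
  std::vector<double> X = to_colmajor(Xin);
  NumericVector out(n, init);
  for (int t = 0; t < T; ++t) {
    NumericMatrix M = trees[t];
    int nn = M.nrow();
    const double* Mp = M.begin();
    for (int i = 0; i < n; ++i)
      out[i] += lr * predict_row(Mp, nn, &X[0], n, i);
  }
  return out;
}
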
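// Regression random forest: bagged CART trees with per-node feature
// subsampling, grown to a minimum node size, returning mean-decrease-in-
// node-impurity importance and out-of-bag predictions.
//
// Trees are not stored: out-of-bag samples are routed down each tree while
// it is grown, which keeps memory flat and is enough for importance and OOB
// error. Uses R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// Best SSE-reducing split among `mtry` randomly drawn features.
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& idx, int mtry,
                       std::vector<int>& feat_pool) {
  const int m = static_cast<int>(idx.size());
  const int p = X.ncol();
  double sum_all = 0.0;
  for (int i : idx) sum_all += y[i];
  const double base = sum_all * sum_all / m;

  // partial Fisher-Yates over the feature pool
  for (int k = 0; k < mtry; ++k) {
    int j = k + static_cast<int>(unif_rand() * (p - k));
    if (j >= p) j = p - 1;
    std::swap(feat_pool[k], feat_pool[j]);
  }

  SplitResult best;
  std::vector<std::pair<double, double>> xy(m);
  for (int k = 0; k < mtry; ++k) {
    const int f = feat_pool[k];
    for (int i = 0; i < m; ++i)
      xy[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;  // constant in node
    double sum_left = 0.0;
    for (int i = 0; i < m - 1; ++i) {
      sum_left += xy[i].second;
      if (xy[i].first == xy[i + 1].first) continue;     // no gap to split
      const double nl = i + 1, nr = m - nl;
      const double sr = sum_all - sum_left;
      const double gain = sum_left * sum_left / nl + sr * sr / nr - base;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (xy[i].first + xy[i + 1].first);
      }
    }
  }
  return best;
}

void grow_node(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& inbag, std::vector<int>& oob,
               int mtry, int min_node, std::vector<int>& feat_pool,
               NumericVector& importance, NumericVector& oob_sum,
               IntegerVector& oob_count) {
  const int m = static_cast<int>(inbag.size());
  double s = 0.0, ss = 0.0;
  for (int i : inbag) { s += y[i]; ss += y[i] * y[i]; }
  const double mean = s / m;
  const double sse = ss - s * s / m;

  SplitResult sp;
  if (m > min_node && sse > 1e-12)
    sp = best_split(X, y, inbag, mtry, feat_pool);

  if (sp.feature < 0) {  // leaf: emit prediction for routed OOB samples
    for (int i : oob) { oob_sum[i] += mean; oob_count[i] += 1; }
    return;
  }
  importance[sp.feature] += sp.gain;

  std::vector<int> in_l, in_r, oob_l, oob_r;
  for (int i : inbag)
    (X(i, sp.feature) <= sp.threshold ? in_l : in_r).push_back(i);
  for (int i : oob)
    (X(i, sp.feature) <= sp.threshold ? oob_l : oob_r).push_back(i);
  grow_node(X, y, in_l, oob_l, mtry, min_node, feat_pool,
            importance, oob_sum, oob_count);
  grow_node(X, y, in_r, oob_r, mtry, min_node, feat_pool,
            importance, oob_sum, oob_count);
}

}  // namespace

// [[Rcpp::export]]
List rf_regression_cpp(NumericMatrix X, NumericVector y, int n_trees,
                       int mtry, int min_node) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  NumericVector importance(p);
  NumericVector oob_sum(n);
  IntegerVector oob_count(n);
  std::vector<int> feat_pool(p);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<char> drawn(n, 0);
    std::vector<int> inbag;
    inbag.reserve(n);
    for (int i = 0; i < n; ++i) {
      int k = static_cast<int>(unif_rand() * n);
      if (k >= n) k = n - 1;
      inbag.push_back(k);
      drawn[k] = 1;
    }
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!drawn[i]) oob.push_back(i);
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    grow_node(X, y, inbag, oob, mtry, min_node, feat_pool,
              importance, oob_sum, oob_count);
  }

  NumericVector oob_pred(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_count[i] > 0) oob_pred[i] = oob_sum[i] / oob_count[i];
  for (int j = 0; j < p; ++j) importance[j] /= n_trees;

  return List::create(_["importance"] = importance,
                      _["oob_prediction"] = oob_pred);
}
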
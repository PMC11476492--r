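#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Minimal weighted CART used by the tree ensembles (random forest, gradient
// boosting, AdaBoost). One criterion serves both tasks: weighted squared error
// about the node mean, which for binary 0/1 responses is proportional to the
// Gini impurity. Leaf value = weighted mean of y (class-1 probability for
// classification). mtry candidate features are drawn per split with R's RNG so
// set.seed() governs reproducibility.

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> value;     // weighted mean of y in node
  std::vector<double> nw;        // weighted n in node
};

class Builder {
public:
  const NumericMatrix &X;
  const NumericVector &y, &w;
  int mtry, max_depth, min_split, min_bucket;
  Tree tree;
  std::vector<double> importance; // summed SSE decrease per feature

  Builder(const NumericMatrix &X_, const NumericVector &y_,
          const NumericVector &w_, int mtry_, int max_depth_, int min_split_,
          int min_bucket_)
      : X(X_), y(y_), w(w_), mtry(mtry_), max_depth(max_depth_),
        min_split(min_split_), min_bucket(min_bucket_),
        importance(X_.ncol(), 0.0) {}

  int build(std::vector<int> &idx, int depth) {
    double sw = 0, sy = 0, sy2 = 0;
    for (int i : idx) {
      sw += w[i];
      sy += w[i] * y[i];
      sy2 += w[i] * y[i] * y[i];
    }
    double mean = sy / sw;
    double sse = sy2 - sy * sy / sw; // weighted SSE about the mean

    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.value.push_back(mean);
    tree.nw.push_back(sw);

    int n = (int)idx.size();
    if (depth >= max_depth || n < min_split || sse <= 1e-12)
      return node;

    // sample mtry candidate features without replacement (partial Fisher-Yates)
    int d = X.ncol();
    std::vector<int> feats(d);
    for (int j = 0; j < d; ++j) feats[j] = j;
    int ncand = std::min(mtry, d);
    for (int j = 0; j < ncand; ++j) {
      int k = j + (int)(unif_rand() * (d - j));
      if (k >= d) k = d - 1;
      std::swap(feats[j], feats[k]);
    }

    int best_f = -1, best_nl = 0;
    double best_gain = 1e-12, best_thr = 0.0;
    std::vector<int> ord(idx);
    for (int jj = 0; jj < ncand; ++jj) {
      int f = feats[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double swl = 0, syl = 0;
      for (int p = 0; p < n - 1; ++p) {
        int i = ord[p];
        swl += w[i];
        syl += w[i] * y[i];
        if (X(ord[p], f) == X(ord[p + 1], f)) continue; // not a boundary
        int nl = p + 1, nr = n - nl;
        if (nl < min_bucket || nr < min_bucket) continue;
        double swr = sw - swl, syr = sy - syl;
        if (swl <= 0 || swr <= 0) continue;
        // SSE decrease = syl^2/swl + syr^2/swr - sy^2/sw
        double gain = syl * syl / swl + syr * syr / swr - sy * sy / sw;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = X(ord[p], f) / 2.0 + X(ord[p + 1], f) / 2.0;
          best_nl = nl;
        }
      }
    }
    if (best_f < 0)
      return node;

    importance[best_f] += best_gain;
    std::vector<int> li, ri;
    li.reserve(best_nl);
    ri.reserve(n - best_nl);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty())
      return node; // midpoint degenerated numerically
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = build(li, depth + 1);
    tree.right[node] = build(ri, depth + 1);
    return node;
  }
};

inline int descend(const IntegerVector &feature, const NumericVector &threshold,
                   const IntegerVector &left, const IntegerVector &right,
                   const NumericMatrix &X, int i) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return node;
}

} // namespace

// [[Rcpp::export]]
List cart_grow(NumericMatrix X, NumericVector y, NumericVector w, int mtry,
               int max_depth, int min_split, int min_bucket) {
  if (X.nrow() != y.size() || X.nrow() != w.size())
    stop("X, y, w dimensions disagree");
  if (X.nrow() == 0)
    stop("empty training set");
  RNGScope scope;
  Builder b(X, y, w, mtry, max_depth, min_split, min_bucket);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  b.build(idx, 0);
  return List::create(
      _["feature"] = wrap(b.tree.feature), _["threshold"] = wrap(b.tree.threshold),
      _["left"] = wrap(b.tree.left), _["right"] = wrap(b.tree.right),
      _["value"] = wrap(b.tree.value), _["nw"] = wrap(b.tree.nw),
      _["importance"] = wrap(b.importance));
}

// [[Rcpp::export]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = value[descend(feature, threshold, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector cart_leaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  IntegerVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    out[i] = descend(feature, threshold, left, right, X, i);
  return out;
}
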
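// Single classification tree (CART): greedy binary splits on Gini impurity,
// unlimited depth, no pruning. Deterministic: features scanned in order,
// thresholds at midpoints of consecutive distinct values, first best split
// kept; leaves predict the majority class (ties -> smallest class index).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // child node ids
  int cls;         // leaf prediction
};

static double gini(const std::vector<int>& counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t c = 0; c < counts.size(); ++c) {
    double p = (double)counts[c] / n;
    g -= p * p;
  }
  return g;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& lab;
  int ncls, min_split;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& lab_, int ncls_,
              int min_split_)
      : X(X_), lab(lab_), ncls(ncls_), min_split(min_split_) {}

  int majority(const std::vector<int>& idx) {
    std::vector<int> counts(ncls, 0);
    for (size_t i = 0; i < idx.size(); ++i) counts[lab[idx[i]]]++;
    int best = 0;
    for (int c = 1; c < ncls; ++c)
      if (counts[c] > counts[best]) best = c;
    return best;
  }

  int build(std::vector<int>& idx) {
    int n = idx.size();
    std::vector<int> counts(ncls, 0);
    for (int i = 0; i < n; ++i) counts[lab[idx[i]]]++;
    int nonzero = 0;
    for (int c = 0; c < ncls; ++c) nonzero += counts[c] > 0;
    int id = nodes.size();
    nodes.push_back(Node());
    Node& leaf = nodes[id];
    leaf.feature = -1;
    leaf.cls = majority(idx);
    leaf.left = leaf.right = -1;
    leaf.threshold = 0.0;
    if (nonzero <= 1 || n < min_split) return id;

    double parent_imp = gini(counts, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    int d = X.ncol();
    std::vector<std::pair<double, int> > vals(n);
    for (int f = 0; f < d; ++f) {
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), lab[idx[i]]);
      std::sort(vals.begin(), vals.end());
      std::vector<int> lc(ncls, 0), rc(counts);
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second]++;
        rc[vals[i].second]--;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double imp = (nl * gini(lc, nl) + nr * gini(rc, nr)) / n;
        double gain = parent_imp - imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
        }
      }
    }
    if (best_f < 0) return id; // no useful split (e.g. duplicated rows)

    std::vector<int> left_idx, right_idx;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_f) <= best_thr) left_idx.push_back(idx[i]);
      else right_idx.push_back(idx[i]);
    }
    if (left_idx.empty() || right_idx.empty()) return id;
    int l = build(left_idx);
    int r = build(right_idx);
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

// [[Rcpp::export(name = ".cart_fit_predict")]]
IntegerVector cart_fit_predict(NumericMatrix X, IntegerVector lab,
                               NumericMatrix Xtest, int min_split = 2) {
  int n = X.nrow(), nt = Xtest.nrow();
  int ncls = 0;
  for (int i = 0; i < n; ++i) ncls = std::max(ncls, lab[i] + 1);
  TreeBuilder tb(X, lab, ncls, min_split);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int root = tb.build(idx);
  IntegerVector pred(nt);
  for (int t = 0; t < nt; ++t) {
    int cur = root;
    while (tb.nodes[cur].feature >= 0) {
      cur = (Xtest(t, tb.nodes[cur].feature) <= tb.nodes[cur].threshold)
                ? tb.nodes[cur].left
                : tb.nodes[cur].right;
    }
    pred[t] = tb.nodes[cur].cls;
  }
  return pred;
}
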
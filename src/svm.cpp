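// RBF-kernel C-SVC trained by SMO (maximal-violating-pair working set
// selection), with one-vs-one voting for the multi-class case.
// Deterministic: fixed iteration order, ties in the vote broken by the
// smallest class index.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double rbf(const double* a, const double* b, int d, double gamma) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = a[k] - b[k];
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

struct BinarySVM {
  std::vector<double> alpha; // alpha_i * y_i stored separately below
  std::vector<int> y;        // +1 / -1
  std::vector<int> idx;      // row indices into the training matrix
  double b;
};

// Train a binary C-SVC on the rows `sub` of X (column-major n x d access via
// pointers), labels y in {+1,-1}.
static BinarySVM smo_train(const NumericMatrix& X, const std::vector<int>& sub,
                           const std::vector<int>& y, double C, double gamma,
                           double tol, int max_iter) {
  int n = sub.size(), d = X.ncol(), N = X.nrow();
  // row-major copies of the subset for cache-friendly kernels
  std::vector<double> rows((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) rows[(size_t)i * d + k] = X[(size_t)k * N + sub[i]];
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = rbf(&rows[(size_t)i * d], &rows[(size_t)j * d], d, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }
  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G_i = sum_j a_j y_i y_j K - 1
  for (int it = 0; it < max_iter; ++it) {
    // maximal violating pair
    int i = -1, j = -1;
    double gmax = -1e30, gmin = 1e30;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;
    double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
           Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;
    double ai_old = alpha[i], aj_old = alpha[j];
    int s = y[i] * y[j];
    // bounds for alpha_j
    double L, H;
    if (s < 0) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    // E_i - E_j = y_i G_i - y_j G_j
    double delta = y[j] * (y[i] * G[i] - y[j] * G[j]) / eta;
    double aj = std::min(std::max(aj_old + delta, L), H);
    double ai = ai_old + s * (aj_old - aj);
    double dai = ai - ai_old, daj = aj - aj_old;
    if (std::fabs(daj) < 1e-15) break;
    alpha[i] = ai;
    alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * dai * K[(size_t)i * n + t] +
                      y[j] * daj * K[(size_t)j * n + t]);
  }
  // intercept from free support vectors (fallback: midpoint of the bounds)
  double bsum = 0.0; int nfree = 0;
  double up = -1e30, lowv = 1e30;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool isup = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    bool islow = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
    if (isup && v > up) up = v;
    if (islow && v < lowv) lowv = v;
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { bsum += v; ++nfree; }
  }
  BinarySVM m;
  m.b = (nfree > 0) ? bsum / nfree : (up + lowv) / 2.0;
  m.y = y;
  m.idx = sub;
  m.alpha = alpha;
  return m;
}

// [[Rcpp::export(name = ".svm_ovo")]]
IntegerVector svm_ovo(NumericMatrix X, IntegerVector lab, NumericMatrix Xtest,
                      double C, double gamma, double tol = 1e-3,
                      int max_iter_per_sample = 300) {
  int n = X.nrow(), d = X.ncol(), nt = Xtest.nrow();
  int ncls = 0;
  for (int i = 0; i < n; ++i) ncls = std::max(ncls, lab[i] + 1);
  if (ncls < 2) stop("need at least 2 classes");
  std::vector<std::vector<double> > test(nt, std::vector<double>(d));
  for (int i = 0; i < nt; ++i)
    for (int k = 0; k < d; ++k) test[i][k] = Xtest(i, k);
  std::vector<std::vector<int> > votes(nt, std::vector<int>(ncls, 0));
  for (int c1 = 0; c1 < ncls; ++c1) {
    for (int c2 = c1 + 1; c2 < ncls; ++c2) {
      std::vector<int> sub, y;
      for (int i = 0; i < n; ++i) {
        if (lab[i] == c1) { sub.push_back(i); y.push_back(1); }
        else if (lab[i] == c2) { sub.push_back(i); y.push_back(-1); }
      }
      if (sub.empty()) continue;
      BinarySVM m = smo_train(X, sub, y, C, gamma, tol,
                              max_iter_per_sample * (int)sub.size());
      int ns = sub.size();
      std::vector<double> srows((size_t)ns * d);
      for (int i = 0; i < ns; ++i)
        for (int k = 0; k < d; ++k) srows[(size_t)i * d + k] = X(sub[i], k);
      for (int t = 0; t < nt; ++t) {
        double f = m.b;
        for (int i = 0; i < ns; ++i) {
          if (m.alpha[i] > 1e-12)
            f += m.alpha[i] * m.y[i] *
                 rbf(&srows[(size_t)i * d], test[t].data(), d, gamma);
        }
        votes[t][f >= 0 ? c1 : c2]++;
      }
    }
  }
  IntegerVector pred(nt);
  for (int t = 0; t < nt; ++t) {
    int best = 0;
    for (int c = 1; c < ncls; ++c)
      if (votes[t][c] > votes[t][best]) best = c; // ties -> smallest index
    pred[t] = best;
  }
  return pred;
}

// Euclidean k-nearest-neighbor prediction; distance ties resolved by training
// index order, vote ties by the smallest class index.
// [[Rcpp::export(name = ".knn_predict")]]
IntegerVector knn_predict(NumericMatrix X, IntegerVector lab,
                          NumericMatrix Xtest, int k) {
  int n = X.nrow(), d = X.ncol(), nt = Xtest.nrow();
  if (k > n) stop("k exceeds the number of training samples");
  int ncls = 0;
  for (int i = 0; i < n; ++i) ncls = std::max(ncls, lab[i] + 1);
  IntegerVector pred(nt);
  std::vector<std::pair<double, int> > dist(n);
  for (int t = 0; t < nt; ++t) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int kk = 0; kk < d; ++kk) {
        double diff = X(i, kk) - Xtest(t, kk);
        s += diff * diff;
      }
      dist[i] = std::make_pair(s, i);
    }
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());
    std::vector<int> votes(ncls, 0);
    for (int i = 0; i < k; ++i) votes[lab[dist[i].second]]++;
    int best = 0;
    for (int c = 1; c < ncls; ++c)
      if (votes[c] > votes[best]) best = c;
    pred[t] = best;
  }
  return pred;
}
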
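// Burg maximum-entropy (autoregressive) spectral estimation.
//
// The AR coefficients are obtained by recursion on the reflection
// coefficients that minimize the summed forward and backward prediction error
// power; the spectrum is the AR transfer function evaluated at the requested
// frequencies:  P(f) = E_p / |1 + sum_k a_k e^{-i2pi f k/fs}|^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct BurgWork {
  std::vector<double> f, b, a, a_prev;
};

// Fit AR(p) by Burg recursion. Returns innovation variance; fills w.a with
// coefficients (sign convention A(z) = 1 + sum a_k z^-k, w.a[0] == 1).
static double burg_fit(const double* x, int n, int p, BurgWork& w) {
  w.f.assign(x, x + n);
  w.b.assign(x, x + n);
  w.a.assign(p + 1, 0.0);
  w.a_prev.assign(p + 1, 0.0);
  w.a[0] = 1.0;
  double* f = w.f.data();
  double* b = w.b.data();
  double E = 0.0;
  for (int i = 0; i < n; ++i) E += x[i] * x[i];
  E /= n;
  if (E <= 0.0) return 0.0; // degenerate all-zero epoch
  for (int m = 1; m <= p; ++m) {
    double num = 0.0, den = 0.0;
    for (int i = m; i < n; ++i) {
      num += f[i] * b[i - 1];
      den += f[i] * f[i] + b[i - 1] * b[i - 1];
    }
    double k = (den > 0.0) ? -2.0 * num / den : 0.0;
    for (int i = 0; i <= m; ++i) w.a_prev[i] = w.a[i];
    for (int i = 1; i < m; ++i) w.a[i] = w.a_prev[i] + k * w.a_prev[m - i];
    w.a[m] = k;
    for (int i = n - 1; i >= m; --i) {
      double fi = f[i];
      f[i] = fi + k * b[i - 1];
      b[i] = b[i - 1] + k * fi;
    }
    E *= (1.0 - k * k);
    if (E <= 0.0) { E = 0.0; break; }
  }
  return E;
}

// cos/sin tables: trig[j*(p+1)+k] for frequency j, lag k.
static void trig_tables(const std::vector<double>& freqs, int p, double fs,
                        std::vector<double>& ct, std::vector<double>& st) {
  int nf = freqs.size();
  ct.resize((size_t)nf * (p + 1));
  st.resize((size_t)nf * (p + 1));
  for (int j = 0; j < nf; ++j) {
    double w = 2.0 * M_PI * freqs[j] / fs;
    for (int k = 0; k <= p; ++k) {
      ct[(size_t)j * (p + 1) + k] = std::cos(w * k);
      st[(size_t)j * (p + 1) + k] = std::sin(w * k);
    }
  }
}

static void ar_psd(const std::vector<double>& a, int p, double E,
                   const std::vector<double>& ct, const std::vector<double>& st,
                   int nf, double* out) {
  if (E <= 0.0) {
    for (int j = 0; j < nf; ++j) out[j] = 0.0;
    return;
  }
  for (int j = 0; j < nf; ++j) {
    const double* c = &ct[(size_t)j * (p + 1)];
    const double* s = &st[(size_t)j * (p + 1)];
    double re = 0.0, im = 0.0;
    for (int k = 0; k <= p; ++k) {
      re += a[k] * c[k];
      im -= a[k] * s[k];
    }
    double mag2 = re * re + im * im;
    out[j] = (mag2 > 0.0) ? E / mag2 : 0.0;
  }
}

// [[Rcpp::export(name = ".burg_psd")]]
NumericVector burg_psd_cpp(NumericVector x, int order, NumericVector freqs,
                           double fs) {
  if ((int)x.size() < 2 * order)
    stop("epoch length must be at least 2 * order");
  BurgWork w;
  double E = burg_fit(x.begin(), x.size(), order, w);
  std::vector<double> fr(freqs.begin(), freqs.end()), ct, st;
  trig_tables(fr, order, fs, ct, st);
  NumericVector out(freqs.size());
  ar_psd(w.a, order, E, ct, st, freqs.size(), out.begin());
  return out;
}

// Band powers for all epochs of one channel, reading epochs straight from the
// continuous channel signal. Epoch i starts at starts[i] (0-based); samples
// beyond seg_ends[i] are filled by reflection about the segment boundary.
// band_lo/band_hi are half-open [lo, hi) integer-Hz bins.
// [[Rcpp::export(name = ".burg_band_channel")]]
NumericMatrix burg_band_channel(NumericVector x, IntegerVector starts,
                                IntegerVector seg_ends, int len, int order,
                                double fs, IntegerVector band_lo,
                                IntegerVector band_hi) {
  int nep = starts.size(), nb = band_lo.size();
  if (len < 2 * order) stop("epoch length must be at least 2 * order");
  std::vector<double> freqs(100), ct, st;
  for (int j = 0; j < 100; ++j) freqs[j] = j + 1;
  trig_tables(freqs, order, fs, ct, st);
  NumericMatrix out(nep, nb);
  BurgWork w;
  std::vector<double> ep(len), psd(100);
  for (int i = 0; i < nep; ++i) {
    int s = starts[i], e = seg_ends[i];
    for (int k = 0; k < len; ++k) {
      int g = s + k;
      if (g >= e) g = 2 * e - g - 1; // reflect about the segment boundary
      ep[k] = x[g];
    }
    double E = burg_fit(ep.data(), len, order, w);
    ar_psd(w.a, order, E, ct, st, 100, psd.data());
    for (int b = 0; b < nb; ++b) {
      double sum = 0.0;
      for (int f = band_lo[b]; f < band_hi[b]; ++f) sum += psd[f - 1];
      out(i, b) = sum;
    }
  }
  return out;
}
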
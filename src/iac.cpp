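#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Population z-score in place; returns false (all zeros) for a
// zero-variance series, mirroring the R reference path's handling of
// collinear pairs.
static bool zscore_pop_inplace(std::vector<double>& x) {
  const int n = static_cast<int>(x.size());
  double mu = 0.0;
  for (int t = 0; t < n; ++t) mu += x[t];
  mu /= n;
  double ss = 0.0;
  for (int t = 0; t < n; ++t) {
    const double d = x[t] - mu;
    ss += d * d;
  }
  const double sd = std::sqrt(ss / n);
  if (sd <= 1e-14 * std::max(std::fabs(mu), 1.0)) {
    std::fill(x.begin(), x.end(), 0.0);
    return false;
  }
  for (int t = 0; t < n; ++t) x[t] = (x[t] - mu) / sd;
  return true;
}

static double median_of(std::vector<double> v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.end());
  return 0.5 * (hi + v[n / 2 - 1]);
}

// Global average-strength time series of the (optionally orthogonalized)
// instantaneous amplitude correlation, computed without materialising the
// pairs x samples tensor. `re`/`im` hold the analytic signal of one band,
// channels x samples, already restricted to the retained span.
// [[Rcpp::export]]
NumericVector cpp_as_series(NumericMatrix re, NumericMatrix im,
                            bool orthogonalize) {
  const int n = re.nrow();
  const int T = re.ncol();
  if (n < 2) stop("at least 2 channels are required");
  if (im.nrow() != n || im.ncol() != T) stop("re/im shape mismatch");

  // contiguous per-channel copies (the input is channels x samples, so a
  // channel's samples are strided in memory), plus envelopes and z-scores
  std::vector<std::vector<double> > rex(n, std::vector<double>(T));
  std::vector<std::vector<double> > imx(n, std::vector<double>(T));
  std::vector<std::vector<double> > env(n, std::vector<double>(T));
  std::vector<std::vector<double> > zenv(n);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) {
      const double a = re(i, t), b = im(i, t);
      rex[i][t] = a;
      imx[i][t] = b;
      env[i][t] = std::sqrt(a * a + b * b);
    }
    zenv[i] = env[i];
    if (!zscore_pop_inplace(zenv[i])) stop("constant (zero-variance) channel");
  }

  NumericVector as(T);
  const double denom = static_cast<double>(n) * (n - 1);

  if (!orthogonalize) {
    for (int t = 0; t < T; ++t) {
      double s = 0.0, q = 0.0;
      for (int i = 0; i < n; ++i) {
        const double z = zenv[i][t];
        s += z;
        q += z * z;
      }
      as[t] = (s * s - q) / denom;
    }
    return as;
  }

  std::vector<double> acc(T, 0.0), invm(T), e(T);
  for (int j = 0; j < n; ++j) {
    const double floor_j = 1e-12 * median_of(env[j]);
    const double* rj = rex[j].data();
    const double* ij = imx[j].data();
    for (int t = 0; t < T; ++t) {
      invm[t] = 1.0 / std::max(env[j][t], floor_j);
    }
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      // envelope of channel i orthogonalized to channel j:
      // |Im(a_i * conj(a_j))| / |a_j|
      const double* ri = rex[i].data();
      const double* ii = imx[i].data();
      for (int t = 0; t < T; ++t) {
        e[t] = std::fabs(ii[t] * rj[t] - ri[t] * ij[t]) * invm[t];
      }
      if (!zscore_pop_inplace(e)) continue;  // collinear pair: contributes 0
      const double* zj = zenv[j].data();
      for (int t = 0; t < T; ++t) acc[t] += e[t] * zj[t];
    }
  }
  for (int t = 0; t < T; ++t) as[t] = acc[t] / denom;
  return as;
}
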
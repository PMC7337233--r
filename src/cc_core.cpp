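#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Normalized 2D cross-correlation of a T x F template against an N x F series.
// CC(l) is the Pearson correlation between the flattened template and the
// flattened window series[l..l+T-1, ], both treated as T*F-vectors.
// Window sums/sums-of-squares come from prefix sums over row totals; the
// cross term is a direct dot product per lag (contiguous down each column).
// Zero-variance windows yield CC = 0 and are counted, not propagated as NaN.
// [[Rcpp::export]]
List cc_core(NumericMatrix series, NumericMatrix tmpl) {
  const int N = series.nrow(), F = series.ncol(), T = tmpl.nrow();
  if (tmpl.ncol() != F) stop("feature count mismatch");
  if (N < T) stop("series shorter than template");
  const int L = N - T + 1;
  const double TF = static_cast<double>(T) * F;

  const double *x = series.begin();
  const double *t = tmpl.begin();

  // template mean and centered sum of squares
  double tsum = 0.0;
  for (int k = 0; k < T * F; ++k) tsum += t[k];
  const double tmean = tsum / TF;
  double tss = 0.0;
  for (int k = 0; k < T * F; ++k) {
    const double d = t[k] - tmean;
    tss += d * d;
  }
  if (tss <= 0.0) stop("template has zero variance");

  // prefix sums of per-bin row sums and row sums of squares
  std::vector<double> r1(N + 1, 0.0), r2(N + 1, 0.0);
  for (int i = 0; i < N; ++i) {
    double s = 0.0, ss = 0.0;
    for (int f = 0; f < F; ++f) {
      const double v = x[i + static_cast<R_xlen_t>(f) * N];
      s += v;
      ss += v * v;
    }
    r1[i + 1] = r1[i] + s;
    r2[i + 1] = r2[i] + ss;
  }

  NumericVector cc(L);
  int n_zero_var = 0;
  const double tiny = 1e-300;
  for (int l = 0; l < L; ++l) {
    double dot = 0.0;
    for (int f = 0; f < F; ++f) {
      const double *xp = x + static_cast<R_xlen_t>(f) * N + l;
      const double *tp = t + static_cast<R_xlen_t>(f) * T;
      double acc = 0.0;
      for (int i = 0; i < T; ++i) acc += xp[i] * tp[i];
      dot += acc;
    }
    const double S1 = r1[l + T] - r1[l];
    const double S2 = r2[l + T] - r2[l];
    const double wss = S2 - S1 * S1 / TF;
    if (wss <= tiny) {
      cc[l] = 0.0;
      ++n_zero_var;
      continue;
    }
    // sum((x - mx)(t - mt)) = dot - tmean * S1, since cross terms cancel
    double v = (dot - tmean * S1) / std::sqrt(wss * tss);
    if (v > 1.0) v = 1.0;
    if (v < -1.0) v = -1.0;
    cc[l] = v;
  }
  return List::create(_["cc"] = cc, _["n_zero_var"] = n_zero_var);
}
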
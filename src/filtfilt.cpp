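#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter, in place. a[0] must be 1.
static void df2t(const std::vector<double>& b, const std::vector<double>& a,
                 std::vector<double>& x, std::vector<double> z) {
  const int n = static_cast<int>(a.size()) - 1;
  const size_t T = x.size();
  for (size_t t = 0; t < T; ++t) {
    const double xt = x[t];
    const double yt = b[0] * xt + z[0];
    for (int k = 0; k < n; ++k) {
      const double zk1 = (k < n - 1) ? z[k + 1] : 0.0;
      z[k] = b[k + 1] * xt + zk1 - a[k + 1] * yt;
    }
    x[t] = yt;
  }
}

// Zero-phase (forward-backward) filtering of each column of x.
// Columns are extended by `pad` samples of odd reflection at both ends and
// each pass starts from the steady-state response to the first sample
// (state zi scaled by that sample), so a constant input maps to its
// zero-frequency gain with no transient.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a, NumericMatrix x,
                           int pad, NumericVector zi) {
  const int T = x.nrow(), P = x.ncol();
  if (pad < 1 || pad > T - 1) stop("pad must be in [1, nrow(x) - 1]");
  const std::vector<double> bv = as<std::vector<double> >(b);
  const std::vector<double> av = as<std::vector<double> >(a);
  const std::vector<double> zv = as<std::vector<double> >(zi);
  const int n = static_cast<int>(av.size()) - 1;
  if (static_cast<int>(zv.size()) != n) stop("zi has wrong length");
  NumericMatrix out(T, P);
  const int Tp = T + 2 * pad;
  std::vector<double> w(Tp), zs(n);
  for (int j = 0; j < P; ++j) {
    for (int i = 0; i < pad; ++i) w[i] = 2.0 * x(0, j) - x(pad - i, j);
    for (int i = 0; i < T; ++i) w[pad + i] = x(i, j);
    for (int i = 0; i < pad; ++i) w[pad + T + i] = 2.0 * x(T - 1, j) - x(T - 2 - i, j);
    for (int k = 0; k < n; ++k) zs[k] = zv[k] * w[0];
    df2t(bv, av, w, zs);
    std::reverse(w.begin(), w.end());
    for (int k = 0; k < n; ++k) zs[k] = zv[k] * w[0];
    df2t(bv, av, w, zs);
    std::reverse(w.begin(), w.end());
    for (int i = 0; i < T; ++i) out(i, j) = w[pad + i];
  }
  return out;
}
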
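#include <Rcpp.h>
using namespace Rcpp;

// One biquad, direct form II transposed, with initial state z scaled for a
// step of height x0 (steady-state initial conditions, so forward-backward
// filtering does not ring at the edges).
static void biquad(const double *b, const double *a, std::vector<double> &x) {
  const size_t n = x.size();
  // steady-state step-response state (lfilter_zi for order 2)
  const double denom = 1.0 + a[1] + a[2];
  const double K = (b[0] + b[1] + b[2]) / (denom != 0.0 ? denom : 1.0);
  const double zi1 = K - b[0];
  const double zi2 = b[2] - a[2] * K;
  double z1 = zi1 * x[0], z2 = zi2 * x[0];
  for (size_t i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z1;
    z1 = b[1] * xi - a[1] * yi + z2;
    z2 = b[2] * xi - a[2] * yi;
    x[i] = yi;
  }
}

// [[Rcpp::export(name = ".sosFiltFiltCpp")]]
NumericVector sosFiltFiltCpp(NumericMatrix sos, NumericVector x) {
  const R_xlen_t n = x.size();
  if (n < 2) return clone(x);
  const R_xlen_t pad = std::min<R_xlen_t>(n - 1, 256);
  std::vector<double> ext(n + 2 * pad);
  // odd reflection padding at both ends
  for (R_xlen_t i = 0; i < pad; ++i) {
    ext[i] = 2.0 * x[0] - x[pad - i];
    ext[n + pad + i] = 2.0 * x[n - 1] - x[n - 2 - i];
  }
  for (R_xlen_t i = 0; i < n; ++i) ext[pad + i] = x[i];
  const int ns = sos.nrow();
  for (int s = 0; s < ns; ++s) {
    double b[3] = { sos(s, 0), sos(s, 1), sos(s, 2) };
    double a[3] = { sos(s, 3), sos(s, 4), sos(s, 5) };
    biquad(b, a, ext);
    std::reverse(ext.begin(), ext.end());
    biquad(b, a, ext);
    std::reverse(ext.begin(), ext.end());
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = ext[pad + i];
  return out;
}
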
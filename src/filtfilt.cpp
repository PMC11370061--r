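#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase IIR filtering of each column of x: forward pass then backward
// pass with a direct-form-II-transposed filter. `zi` holds the steady-state
// filter state for a unit step input; it is scaled by the first (resp. last)
// sample of each pass so that a constant signal passes through unchanged.
// Coefficients are assumed normalized (a[0] == 1).

static inline void df2t_pass(const double* x, double* y, int n,
                             const double* b, const double* a, int nf,
                             const double* zi, double x0) {
  std::vector<double> z(nf - 1);
  for (int k = 0; k < nf - 1; ++k) z[k] = zi[k] * x0;
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nf - 2; ++k) z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
}

// [[Rcpp::export]]
NumericMatrix filtfilt_cpp(NumericVector b, NumericVector a,
                           NumericMatrix x, NumericVector zi) {
  const int n = x.nrow(), nc = x.ncol(), nf = b.size();
  if (a.size() != nf) stop("b and a must have equal length");
  if (zi.size() != nf - 1) stop("zi must have length(b) - 1 elements");
  NumericMatrix y(n, nc);
  std::vector<double> fwd(n), rev(n);
  for (int c = 0; c < nc; ++c) {
    std::vector<double> col(n);
    for (int i = 0; i < n; ++i) col[i] = x(i, c);
    df2t_pass(col.data(), fwd.data(), n, b.begin(), a.begin(), nf, zi.begin(), col[0]);
    std::reverse(fwd.begin(), fwd.end());
    df2t_pass(fwd.data(), rev.data(), n, b.begin(), a.begin(), nf, zi.begin(), fwd[0]);
    std::reverse(rev.begin(), rev.end());
    for (int i = 0; i < n; ++i) y(i, c) = rev[i];
  }
  return y;
}
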
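#include <Rcpp.h>
using namespace Rcpp;

// Multivariate dynamic time warping, symmetric2 step pattern, both
// endpoints constrained to match ("closed" begin and end).
//
// Local cost d(i,j) = Euclidean distance between frame i of `a` and frame j
// of `b` in R^p. Recursion:
//   D(i,j) = min( D(i-1,j)   +   d(i,j),
//                 D(i-1,j-1) + 2*d(i,j),
//                 D(i,j-1)   +   d(i,j) ),  D(1,1) = d(1,1).
// The symmetric2 normalization divides the cumulative cost by N + M.

// [[Rcpp::export]]
List dtw_sym2_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), p = a.ncol();
  if (b.ncol() != p) stop("series must have the same number of coordinates");
  if (n < 1 || m < 1) stop("empty series");

  std::vector<double> prev(m), cur(m), drow(m);

  // local cost for row 0
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) { double t = a(0, k) - b(j, k); s += t * t; }
    drow[j] = std::sqrt(s);
  }
  prev[0] = drow[0];
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + drow[j];

  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) { double t = a(i, k) - b(j, k); s += t * t; }
      drow[j] = std::sqrt(s);
    }
    cur[0] = prev[0] + drow[0];
    for (int j = 1; j < m; ++j) {
      double best = prev[j] + drow[j];
      double diag = prev[j - 1] + 2.0 * drow[j];
      if (diag < best) best = diag;
      double left = cur[j - 1] + drow[j];
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }

  const double dist = prev[m - 1];
  return List::create(_["distance"] = dist,
                      _["normalized"] = dist / double(n + m),
                      _["n"] = n, _["m"] = m);
}

static double dtw_norm_one(const NumericMatrix& a, const NumericMatrix& b) {
  const int n = a.nrow(), m = b.nrow(), p = a.ncol();
  std::vector<double> prev(m), cur(m), drow(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) { double t = a(0, k) - b(j, k); s += t * t; }
    drow[j] = std::sqrt(s);
  }
  prev[0] = drow[0];
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + drow[j];
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) { double t = a(i, k) - b(j, k); s += t * t; }
      drow[j] = std::sqrt(s);
    }
    cur[0] = prev[0] + drow[0];
    for (int j = 1; j < m; ++j) {
      double best = prev[j] + drow[j];
      double diag = prev[j - 1] + 2.0 * drow[j];
      if (diag < best) best = diag;
      double left = cur[j - 1] + drow[j];
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1] / double(n + m);
}

// All unique pairwise normalized distances of a list of segment matrices,
// in combn(n, 2) column order.
// [[Rcpp::export]]
NumericVector dtw_pairwise_cpp(List segs) {
  const int n = segs.size();
  if (n < 2) stop("need at least two segments");
  std::vector<NumericMatrix> mats(n);
  for (int i = 0; i < n; ++i) mats[i] = as<NumericMatrix>(segs[i]);
  const int p = mats[0].ncol();
  for (int i = 1; i < n; ++i)
    if (mats[i].ncol() != p) stop("segments must share the column count");
  NumericVector out(n * (n - 1) / 2);
  int idx = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      out[idx++] = dtw_norm_one(mats[i], mats[j]);
  return out;
}
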
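#include <Rcpp.h>
using namespace Rcpp;

// Column-wise add / multiply of a per-column scalar, without materializing
// the recycled vector (hot path under the conv/norm layers).

// [[Rcpp::export]]
NumericMatrix col_add_cpp(NumericMatrix x, NumericVector v) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double* px = x.begin();
  double* po = out.begin();
  for (int j = 0; j < nc; ++j) {
    const double vj = v[j];
    const double* c = px + (R_xlen_t)j * nr;
    double* o = po + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) o[i] = c[i] + vj;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix col_mul_cpp(NumericMatrix x, NumericVector v) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  const double* px = x.begin();
  double* po = out.begin();
  for (int j = 0; j < nc; ++j) {
    const double vj = v[j];
    const double* c = px + (R_xlen_t)j * nr;
    double* o = po + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) o[i] = c[i] * vj;
  }
  return out;
}

// Leaky-rectifier forward: returns y and the gradient factor in one pass.
// [[Rcpp::export]]
List lrelu_cpp(NumericVector x, double slope) {
  R_xlen_t n = x.size();
  NumericVector y(n), fac(n);
  const double* px = x.begin();
  double* py = y.begin();
  double* pf = fac.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double f = px[i] > 0 ? 1.0 : slope;
    pf[i] = f;
    py[i] = px[i] * f;
  }
  return List::create(_["y"] = y, _["fac"] = fac);
}
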
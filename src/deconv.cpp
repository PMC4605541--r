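#include <Rcpp.h>
using namespace Rcpp;

// Nonnegative AR(1) deconvolution by pool adjacent violators (online
// active-set sweep). Solves
//   min_c 0.5 * sum_t (c_t - y_t)^2 + lam * sum_t (c_t - d * c_{t-1})
//   s.t.  c_t >= d * c_{t-1},  c_t >= 0,
// i.e. the denoised calcium trace whose innovations (spikes) are
// nonnegative. Returns the fitted calcium trace c.
// [[Rcpp::export]]
NumericVector oasis_ar1_cpp(const NumericVector& y, double d, double lam) {
  const int T = y.size();
  std::vector<double> v(T), wgt(T), dl(T);
  std::vector<int> t0(T), len(T);
  int np = 0;  // active pool count
  for (int t = 0; t < T; ++t) {
    // L1 penalty on innovations: each c_t carries lam*(1 - d) except the
    // last bin, whose spike is not followed by a decaying tail.
    double yt = y[t] - lam * (t == T - 1 ? 1.0 : (1.0 - d));
    v[np] = yt; wgt[np] = 1.0; t0[np] = t; len[np] = 1; dl[np] = d;
    ++np;
    while (np > 1 &&
           v[np - 1] / wgt[np - 1] < dl[np - 2] * (v[np - 2] / wgt[np - 2])) {
      // merge pool np-1 into np-2
      v[np - 2] += dl[np - 2] * v[np - 1];
      wgt[np - 2] += dl[np - 2] * dl[np - 2] * wgt[np - 1];
      len[np - 2] += len[np - 1];
      dl[np - 2] *= dl[np - 1];
      --np;
    }
  }
  NumericVector c(T);
  for (int p = 0; p < np; ++p) {
    double cs = v[p] / wgt[p];
    if (cs < 0) cs = 0;
    for (int k = 0; k < len[p]; ++k) {
      c[t0[p] + k] = cs;
      cs *= d;
    }
  }
  return c;
}
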
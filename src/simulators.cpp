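#include <Rcpp.h>
using namespace Rcpp;

// Logistic GLM network simulator.
//
// State update: U[,t] = W %*% S[,t-1] + b (+ GX[,t]); S[i,t] ~ Bern(sigma(U[i,t])).
// Spiking is sparse at physiological rates, so the matrix-vector product is
// accumulated over active presynaptic neurons only. Burn-in bins are run
// (without stimulus) and discarded; the state entering the first kept bin is
// returned as `s0`. Uses R's RNG (caller seeds via set.seed).
// [[Rcpp::export]]
List simulate_glm_cpp(const NumericMatrix& W, const NumericVector& b,
                      const NumericMatrix& GX, int nBins, int burnIn,
                      const IntegerVector& sInit) {
  const int N = W.nrow();
  const bool hasStim = GX.ncol() > 0;
  IntegerMatrix S(N, nBins);
  IntegerVector state = clone(sInit);
  IntegerVector s0(N);
  std::vector<double> u(N);
  for (int t = -burnIn; t < nBins; ++t) {
    for (int i = 0; i < N; ++i) u[i] = b[i];
    for (int j = 0; j < N; ++j) {
      if (state[j]) {
        const double* wj = &W(0, j);
        for (int i = 0; i < N; ++i) u[i] += wj[i];
      }
    }
    if (hasStim && t >= 0) {
      const double* g = &GX(0, t);
      for (int i = 0; i < N; ++i) u[i] += g[i];
    }
    if (t == 0) for (int i = 0; i < N; ++i) s0[i] = state[i];
    for (int i = 0; i < N; ++i) {
      double p = 1.0 / (1.0 + std::exp(-u[i]));
      state[i] = (unif_rand() < p) ? 1 : 0;
    }
    if (t >= 0) for (int i = 0; i < N; ++i) S(i, t) = state[i];
  }
  return List::create(_["S"] = S, _["s0"] = s0);
}

// Discrete-time stochastic leaky integrate-and-fire simulator.
//
// At each bin: U[,t] = W %*% S[,t-1] + b (+ GX[,t]);
//   S[i,t] = I[V[i,t-1] > threshold];
//   V[i,t] = (gamma*V[i,t-1] + (1-gamma)*U[i,t] + eps) * I[S[i,t] == 0].
// The membrane potential is reset to zero in the bin of the spike itself, so
// with threshold >= 0 a spike enforces one bin of absolute refractoriness.
// [[Rcpp::export]]
List simulate_lif_cpp(const NumericMatrix& W, const NumericVector& b,
                      const NumericMatrix& GX, int nBins, int burnIn,
                      double gamma, double noiseSd, double threshold) {
  const int N = W.nrow();
  const bool hasStim = GX.ncol() > 0;
  IntegerMatrix S(N, nBins);
  IntegerVector state(N), s0(N);
  std::vector<double> u(N), v(N, 0.0);
  for (int t = -burnIn; t < nBins; ++t) {
    for (int i = 0; i < N; ++i) u[i] = b[i];
    for (int j = 0; j < N; ++j) {
      if (state[j]) {
        const double* wj = &W(0, j);
        for (int i = 0; i < N; ++i) u[i] += wj[i];
      }
    }
    if (hasStim && t >= 0) {
      const double* g = &GX(0, t);
      for (int i = 0; i < N; ++i) u[i] += g[i];
    }
    if (t == 0) for (int i = 0; i < N; ++i) s0[i] = state[i];
    for (int i = 0; i < N; ++i) {
      int s = (v[i] > threshold) ? 1 : 0;
      state[i] = s;
      double eps = (noiseSd > 0) ? noiseSd * norm_rand() : 0.0;
      v[i] = s ? 0.0 : (gamma * v[i] + (1.0 - gamma) * u[i] + eps);
    }
    if (t >= 0) for (int i = 0; i < N; ++i) S(i, t) = state[i];
  }
  return List::create(_["S"] = S, _["s0"] = s0);
}
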
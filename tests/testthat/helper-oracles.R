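# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# Exact profile loglikelihood: per-neuron 1-D numeric maximization of the
# full GLM loglikelihood over the bias.
exactProfileLogLik <- function(W, raster) {
  S <- spikes(raster)
  Tn <- ncol(S)
  Sprev <- cbind(initialState(raster), S[, -Tn, drop = FALSE])
  storage.mode(S) <- "double"
  sum(vapply(seq_len(nrow(S)), function(i) {
    drive <- as.numeric(W[i, , drop = FALSE] %*% Sprev)
    f <- function(b) {
      u <- drive + b
      sum(S[i, ] * u) - sum(ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u))))
    }
    stats::optimize(f, c(-30, 30), maximum = TRUE, tol = 1e-10)$objective
  }, numeric(1)))
}

# Monte-Carlo estimate of E[log(1 + exp(x))], x ~ N(mu, sigma2).
mcSoftplusIntegral <- function(mu, sigma2, n = 1e6, seed = 99) {
  set.seed(seed)
  x <- stats::rnorm(n, mu, sqrt(sigma2))
  mean(ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x))))
}

# Empirical expected gradient of the exact loglikelihood in W, with its
# per-entry Monte-Carlo standard errors.
mcExpectedGradient <- function(params, raster) {
  S <- spikes(raster)
  Tn <- ncol(S)
  Sprev <- cbind(initialState(raster), S[, -Tn, drop = FALSE])
  storage.mode(S) <- "double"; storage.mode(Sprev) <- "double"
  U <- weightMatrix(params) %*% Sprev + biases(params)
  E <- S - stats::plogis(U)
  G <- tcrossprod(E, Sprev) / Tn
  N <- nrow(S)
  sdG <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    g <- E[i, ] * Sprev[j, ]
    sdG[i, j] <- stats::sd(g) / sqrt(Tn)
  }
  list(grad = G, sd = sdG)
}

# small net + raster used by several files
makeTestNet <- function(N = 10, seed = 1, ...) {
  generateNetwork(networkConfig(N = N, seed = seed, ...))
}
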
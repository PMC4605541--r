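test_that("logistic is exact at closed-form points and stable at extremes", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(log(3)), 0.75)
  expect_equal(logistic(-0.5), 0.37754, tolerance = 1e-5)
  expect_equal(logistic(c(-Inf, Inf)), c(0, 1))
  expect_equal(logistic(800), 1)
  expect_error(logistic(NaN))
})

test_that("generateNetwork respects config invariants", {
  expect_error(networkConfig(N = 20, pConn = 0), "pConn")
  cfg <- networkConfig(N = 50, seed = 42)
  n1 <- generateNetwork(cfg)
  n2 <- generateNetwork(cfg)
  expect_identical(weightMatrix(n1), weightMatrix(n2))
  expect_identical(biases(n1), biases(n2))

  W <- weightMatrix(n1)
  off <- row(W) != col(W)
  # Dale's law: every presynaptic column single-signed off the diagonal
  for (j in seq_len(ncol(W))) {
    wj <- W[-j, j]
    expect_lte(length(unique(sign(wj[wj != 0]))), 1)
  }
  expect_true(all(diag(W) < 0))
  # inhibitory magnitudes stronger in the median
  exc <- W[off][W[off] > 0]; inh <- W[off][W[off] < 0]
  expect_gt(stats::median(abs(inh)), stats::median(exc))
})

test_that("off-diagonal density matches pConn within 3 binomial sd", {
  cfg <- networkConfig(N = 200, pConn = 0.163, seed = 7)
  W <- weightMatrix(generateNetwork(cfg))
  off <- row(W) != col(W)
  n <- sum(off)
  dens <- mean(W[off] != 0)
  expect_lt(abs(dens - 0.163), 3 * sqrt(0.163 * (1 - 0.163) / n))
})

test_that("disconnected GLM reduces to independent Bernoulli rows", {
  net <- networkParams(matrix(0, 4, 4), b = c(0, 0, -0.5, -0.5))
  r <- simulateGLM(net, nBins = 1e5, seed = 5, burnIn = 10)
  rates <- rowMeans(spikes(r))
  sd0 <- sqrt(0.25 / 1e5)
  expect_lt(max(abs(rates[1:2] - 0.5)), 3 * sd0)
  sd1 <- sqrt(0.37754 * (1 - 0.37754) / 1e5)
  expect_lt(max(abs(rates[3:4] - 0.37754)), 3 * sd1)
  # binomial test at alpha = 0.001 per row
  for (i in 1:4) {
    p0 <- c(0.5, 0.5, 0.37754, 0.37754)[i]
    pv <- stats::binom.test(sum(spikes(r)[i, ]), 1e5, p0)$p.value
    expect_gt(pv, 0.001)
  }
})

test_that("simulateGLM is deterministic and binary", {
  net <- makeTestNet(N = 8, seed = 2)
  r1 <- simulateGLM(net, nBins = 500, seed = 11)
  r2 <- simulateGLM(net, nBins = 500, seed = 11)
  expect_identical(spikes(r1), spikes(r2))
  expect_identical(initialState(r1), initialState(r2))
  expect_true(all(spikes(r1) %in% c(0L, 1L)))
})

test_that("self-coupled neuron matches the two-state Markov chain oracle", {
  fx <- makeFixtures(seed = 3)$twoState
  net <- fx$network
  r <- simulateGLM(net, nBins = 2e5, seed = 21, burnIn = 500)
  s <- as.numeric(spikes(r))
  # stationary rate
  nEff <- 2e5 / 5  # conservative effective sample size under autocorrelation
  expect_lt(abs(mean(s) - fx$stationaryRate),
            4 * sqrt(fx$stationaryRate * (1 - fx$stationaryRate) / nEff))
  # conditional spike probability given a spike in the previous bin
  prev <- s[-length(s)]; cur <- s[-1]
  p11 <- mean(cur[prev == 1])
  p11True <- logistic(biases(net) + weightMatrix(net)[1, 1])
  expect_lt(abs(p11 - p11True), 4 * sqrt(p11True * (1 - p11True) / sum(prev)))
})

test_that("GLM conditional spike probabilities match logistic(U)", {
  W <- matrix(c(-1, 1.5, 0.8, -1), 2, 2)
  b <- c(-0.2, -0.6)
  net <- networkParams(W, b)
  r <- simulateGLM(net, nBins = 1.5e5, seed = 31, burnIn = 100)
  S <- spikes(r)
  Tn <- ncol(S)
  prev <- S[, -Tn, drop = FALSE]; cur <- S[, -1, drop = FALSE]
  for (p1 in 0:1) for (p2 in 0:1) {
    sel <- prev[1, ] == p1 & prev[2, ] == p2
    if (sum(sel) < 500) next
    u <- W %*% c(p1, p2) + b
    for (i in 1:2) {
      pHat <- mean(cur[i, sel])
      pTrue <- logistic(u[i])
      expect_lt(abs(pHat - pTrue), 3 * sqrt(pTrue * (1 - pTrue) / sum(sel)))
    }
  }
})

test_that("LIF enforces one-bin refractoriness and subthreshold silence", {
  net <- makeTestNet(N = 10, seed = 4)
  r <- simulateLIF(net, nBins = 2e4, cfg = lifConfig(), seed = 8)
  S <- spikes(r)
  expect_true(all(S %in% c(0L, 1L)))
  consec <- S[, -1] * S[, -ncol(S)]
  expect_equal(sum(consec), 0)

  # deterministic subthreshold dynamics: steady state V = b < threshold
  quiet <- networkParams(matrix(0, 3, 3), b = rep(0.4, 3))
  r0 <- simulateLIF(quiet, nBins = 5000, cfg = lifConfig(noiseSd = 0),
                    seed = 9, burnIn = 200)
  expect_equal(sum(spikes(r0)), 0)
})

test_that("LIF firing rate is nondecreasing in the bias", {
  bGrid <- c(-1, -0.5, 0, 0.5, 1)
  rates <- matrix(0, 20, length(bGrid))
  net <- networkParams(matrix(0, length(bGrid), length(bGrid)), b = bGrid)
  for (s in 1:20) {
    r <- simulateLIF(net, nBins = 3000, cfg = lifConfig(), seed = 100 + s,
                     burnIn = 100)
    rates[s, ] <- rowMeans(spikes(r))
  }
  avg <- colMeans(rates)
  expect_true(all(diff(avg) >= -1e-3))
})
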
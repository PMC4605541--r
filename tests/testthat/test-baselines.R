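test_that("fullLogLik matches closed forms", {
  r1 <- spikeRaster(matrix(1L, 1, 1))
  expect_equal(fullLogLik(matrix(0, 1, 1), 0, r1), log(0.5))

  net <- makeTestNet(N = 5, seed = 1)
  r <- simulateGLM(net, nBins = 400, seed = 2)
  expect_equal(fullLogLik(matrix(0, 5, 5), rep(0, 5), r), -5 * 400 * log(2))
})

test_that("scaled exact and profile ELL loglikelihoods agree at the truth", {
  set.seed(3)
  W <- matrix(rnorm(9, sd = 0.5), 3, 3)
  net <- networkParams(W, rnorm(3, -1, 0.3))
  r <- simulateGLM(net, nBins = 5e4, seed = 4)
  st <- exactMoments(r)
  a <- fullLogLik(W, biases(net), r) / 5e4
  b <- profileELL(W, st) / 5e4
  expect_lt(abs(a - b) / abs(a), 0.03)
})

test_that("fitMAPFull agrees with per-row logistic regression (glm oracle)", {
  # moderate rates keep the design well-conditioned (no flat ridges)
  set.seed(5)
  net <- networkParams(matrix(rnorm(16, sd = 0.5), 4, 4), rnorm(4, -1, 0.3))
  r <- simulateGLM(net, nBins = 2e4, seed = 6)
  fit <- fitMAPFull(r, lambda = 0, tol = 1e-12)
  S <- spikes(r)
  Sprev <- cbind(initialState(r), S[, -ncol(S)])
  for (i in 1:4) {
    g <- suppressWarnings(
      stats::glm(S[i, ] ~ t(Sprev), family = stats::binomial()))
    expect_equal(unname(estimatedWeights(fit)[i, ]),
                 unname(stats::coef(g)[-1]), tolerance = 1e-3)
    expect_equal(unname(estimatedBiases(fit)[i]),
                 unname(stats::coef(g)[1]), tolerance = 1e-3)
  }
})

test_that("fully shrunk full-likelihood fit recovers Bernoulli logits", {
  net <- makeTestNet(N = 5, seed = 7)
  r <- simulateGLM(net, nBins = 3e4, seed = 8)
  fit <- fitMAPFull(r, lambda = 50, penalizeDiagonal = TRUE)
  expect_true(all(estimatedWeights(fit) == 0))
  rates <- rowMeans(spikes(r))
  expect_equal(estimatedBiases(fit), log(rates / (1 - rates)),
               tolerance = 1e-4)
})

test_that("fitMAPFull refuses partial observations", {
  net <- makeTestNet(N = 4, seed = 9)
  r <- simulateGLM(net, nBins = 100, seed = 10)
  m <- makeMask("fully_random", N = 4, nBins = 100, pObs = 0.5, seed = 11)
  expect_error(fitMAPFull(r, mask = m), "fitMAP")
})

test_that("ELL-based and full-likelihood MAP agree at full observation", {
  net <- makeTestNet(N = 10, seed = 12)
  r <- simulateGLM(net, nBins = 1e5, seed = 13)
  st <- exactMoments(r)
  W <- weightMatrix(net)
  off <- row(W) != col(W)
  target <- mean(W[off] != 0)
  fitE <- selectLambda(st, targetSparsity = target, warn = FALSE)$result
  fitF <- fitMAPFull(r, lambda = fitE@lambda)
  We <- estimatedWeights(fitE); Wf <- estimatedWeights(fitF)
  expect_gt(stats::cor(as.numeric(We), as.numeric(Wf)), 0.95)
  nz <- W != 0
  both <- We[nz] != 0
  agree <- mean(sign(We[nz][both]) == sign(Wf[nz][both]))
  expect_gte(agree, 0.95)
})

test_that("gibbsImpute leaves observed data untouched and is seed-stable", {
  net <- makeTestNet(N = 6, seed = 14)
  r <- simulateGLM(net, nBins = 500, seed = 15)
  full <- new("ObservationMask", O = matrix(1L, 6, 500), scheme = "custom",
              pObsTarget = 1)
  out <- gibbsImpute(r, full, weightMatrix(net), biases(net), sweeps = 3,
                     seed = 16)
  expect_identical(spikes(out), spikes(r))

  m <- makeMask("fully_random", N = 6, nBins = 500, pObs = 0.5, seed = 17)
  a <- gibbsImpute(r, m, weightMatrix(net), biases(net), sweeps = 5, seed = 18)
  b <- gibbsImpute(r, m, weightMatrix(net), biases(net), sweeps = 5, seed = 18)
  expect_identical(spikes(a), spikes(b))
  O <- maskMatrix(m)
  expect_identical(spikes(a)[O == 1L], spikes(r)[O == 1L])
})

test_that("with W = 0 the Gibbs conditional is sigma(b)", {
  b <- c(-0.8, 0.4)
  r <- spikeRaster(matrix(0L, 2, 3))
  O <- matrix(1L, 2, 3); O[1, 2] <- 0L
  m <- new("ObservationMask", O = O, scheme = "custom", pObsTarget = 5 / 6)
  draws <- vapply(1:3000, function(s) {
    spikes(gibbsImpute(r, m, matrix(0, 2, 2), b, sweeps = 1, seed = s,
                       init = "zero"))[1, 2]
  }, integer(1))
  p <- logistic(b[1])
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / 3000))
})

test_that("Gibbs marginal matches the exact enumeration oracle", {
  fx <- makeFixtures(seed = 19)$gibbsEnum
  r <- spikeRaster(fx$S, s0 = c(0, 0))
  m <- new("ObservationMask", O = fx$O, scheme = "custom", pObsTarget = 5 / 6)
  # one sweep from a random init draws the single missing site exactly from
  # its full conditional
  draws <- vapply(1:4000, function(s) {
    spikes(gibbsImpute(r, m, fx$W, fx$b, sweeps = 1, seed = s,
                       init = "zero"))[1, 2]
  }, integer(1))
  p <- fx$conditionalP1
  expect_lt(abs(mean(draws) - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("Gibbs chain reaches the enumerated stationary distribution", {
  # two missing entries in a 2 x 3 raster: compare the chain's occupancy of
  # the four completions to the exact conditional by enumeration
  W <- matrix(c(-0.4, 0.9, -1.1, -0.4), 2, 2)
  b <- c(-0.2, 0.1)
  S <- matrix(c(1L, 0L, 0L, 0L, 1L, 1L), 2, 3)
  O <- matrix(1L, 2, 3); O[1, 2] <- 0L; O[2, 2] <- 0L
  logp <- sapply(0:3, function(k) {
    s <- S; s[1, 2] <- k %% 2L; s[2, 2] <- k %/% 2L
    fullLogLik(W, b, spikeRaster(s, s0 = c(0, 0)))
  })
  pExact <- exp(logp - max(logp)); pExact <- pExact / sum(pExact)
  m <- new("ObservationMask", O = O, scheme = "custom", pObsTarget = 2 / 3)
  out <- gibbsImpute(spikeRaster(S, s0 = c(0, 0)), m, W, b, sweeps = 20000,
                     seed = 20, returnSamples = TRUE)
  keep <- seq(100, 20000, by = 5)  # drop burn-in, thin the chain
  states <- out$samples[1, keep] + 2 * out$samples[2, keep]
  obs <- tabulate(states + 1, nbins = 4)
  pv <- suppressWarnings(stats::chisq.test(obs, p = pExact)$p.value)
  expect_gt(pv, 0.001)
})

test_that("emStep is a fixed point under full observation", {
  net <- makeTestNet(N = 8, seed = 21)
  r <- simulateGLM(net, nBins = 5e4, seed = 22)
  st <- exactMoments(r)
  fit <- fitMAP(st, lambda = 2e-4, warn = FALSE)
  full <- new("ObservationMask", O = matrix(1L, 8, 5e4), scheme = "custom",
              pObsTarget = 1)
  fit2 <- emStep(r, full, fit, seed = 23)
  d <- max(abs(estimatedWeights(fit2) - estimatedWeights(fit)))
  expect_lt(d, 1e-3)
  expect_true(all(is.finite(fit2@objTrace)))
})
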
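test_that("gaussianSigmoidIntegral matches closed forms and the MC oracle", {
  expect_equal(gaussianSigmoidIntegral(0, 0), log(2))
  expect_equal(gaussianSigmoidIntegral(0, 8 / pi), sqrt(2) * log(2))
  expect_error(gaussianSigmoidIntegral(0, -1), "nonnegative")
  # stability
  expect_equal(gaussianSigmoidIntegral(800, 0), 800)
  expect_true(is.finite(gaussianSigmoidIntegral(-800, 4)))
  # Monte-Carlo oracle: modest error near the bulk, degrading monotonically
  # as the mean moves into the negative tail
  relerr <- sapply(c(0, -2, -6), function(mu) {
    mc <- mcSoftplusIntegral(mu, 1)
    abs(gaussianSigmoidIntegral(mu, 1) - mc) / mc
  })
  expect_lt(relerr[1], 0.02)
  expect_lt(relerr[2], 0.15)
  expect_true(all(diff(relerr) > 0))
})

test_that("profile ELL at W = 0 is the exact independent-Bernoulli profile", {
  fx <- makeFixtures(seed = 2)$bernoulliNull
  val <- profileELL(matrix(0, 4, 4), fx$stats)
  expect_equal(val, fx$exactProfileELL, tolerance = 1e-12)
  # and it agrees with the brute-force exact profile exactly in this case
  expect_equal(val, exactProfileLogLik(matrix(0, 4, 4), fx$raster),
               tolerance = 1e-7)
})

test_that("profile ELL decomposes over rows of W", {
  net <- makeTestNet(N = 5, seed = 3)
  r <- simulateGLM(net, nBins = 2e4, seed = 4)
  st <- exactMoments(r)
  W <- weightMatrix(net)
  base <- profileELL(matrix(0, 5, 5), st)
  total <- profileELL(W, st)
  parts <- sapply(1:5, function(i) {
    Wi <- matrix(0, 5, 5); Wi[i, ] <- W[i, ]
    profileELL(Wi, st) - base
  })
  expect_equal(total - base, sum(parts), tolerance = 1e-10)
})

test_that("profile ELL tracks the exact profile loglikelihood", {
  # moderate weights: at tiny N the Gaussian-input step is the binding
  # approximation and its error grows with the weight scale
  set.seed(5)
  W <- matrix(rnorm(9, sd = 0.5), 3, 3)
  net <- networkParams(W, rnorm(3, -1, 0.3))
  r <- simulateGLM(net, nBins = 3e4, seed = 6)
  st <- exactMoments(r)
  ell <- profileELL(W, st)
  exact <- exactProfileLogLik(W, r)
  expect_lt(abs(ell - exact) / abs(exact), 0.02)
})

test_that("recoverBias inverts the logit and recovers simulated biases", {
  st5 <- local({
    net <- networkParams(matrix(0, 2, 2), b = c(0, log(1 / 3)))
    exactMoments(simulateGLM(net, nBins = 10, seed = 1))
  })
  # closed forms with W = 0 and exact m
  m <- c(0.5, 0.25)
  stm <- new("MomentStats", m = m, Sigma0 = diag(m * (1 - m)),
             Sigma1 = matrix(0, 2, 2), countsM = rep(10, 2),
             counts0 = matrix(10, 2, 2), counts1 = matrix(9, 2, 2),
             nTime = 10L, binWidth = 0.01, nStim = 0L)
  b <- recoverBias(matrix(0, 2, 2), stm)
  expect_equal(b, c(0, log(1 / 3)))

  # silent neuron error names the neuron
  stm@m[2] <- 0
  expect_error(recoverBias(matrix(0, 2, 2), stm), "2")

  # parameter recovery on a simulated network at the true weights
  set.seed(7)
  W20 <- matrix(rnorm(400, sd = 0.25), 20, 20)
  bTrue <- rnorm(20, -1.2, 0.3)
  net <- networkParams(W20, bTrue)
  r <- simulateGLM(net, nBins = 1e6, seed = 8)
  st <- exactMoments(r)
  bhat <- recoverBias(W20, st)
  expect_lt(sqrt(mean((bhat - bTrue)^2)), 0.1)
})

test_that("objective-mode gradient matches central finite differences", {
  net <- makeTestNet(N = 5, seed = 9)
  r <- simulateGLM(net, nBins = 2e4, seed = 10)
  st <- exactMoments(r)
  set.seed(11)
  W <- matrix(rnorm(25, sd = 0.4), 5, 5)
  G <- ellGradient(W, st, nT = 1, mode = "objective")
  eps <- 1e-5
  for (idx in sample(25, 10)) {
    Wp <- W; Wm <- W
    Wp[idx] <- Wp[idx] + eps; Wm[idx] <- Wm[idx] - eps
    fd <- (profileELL(Wp, st, nT = 1, warn = FALSE) -
           profileELL(Wm, st, nT = 1, warn = FALSE)) / (2 * eps)
    expect_lt(abs(G[idx] - fd), 1e-5 * max(1, abs(fd)))
  }
})

test_that("adjusted gradient reduces to T * Sigma1 at W = 0", {
  net <- makeTestNet(N = 4, seed = 12)
  r <- simulateGLM(net, nBins = 1e4, seed = 13)
  st <- exactMoments(r)
  G <- ellGradient(matrix(0, 4, 4), st, mode = "adjusted")
  expect_equal(G, nTimeBins(st) * momentCov(st, 1), tolerance = 1e-10)
})

test_that("huge L1 with diagonal penalty shrinks everything to exact zero", {
  net <- makeTestNet(N = 6, seed = 14)
  r <- simulateGLM(net, nBins = 2e4, seed = 15)
  st <- exactMoments(r)
  lam <- 1e3 * max(abs(momentCov(st, 1)))
  fit <- fitMAP(st, lambda = lam, penalizeDiagonal = TRUE, warn = FALSE)
  expect_true(all(estimatedWeights(fit) == 0))
})

test_that("null-model fit stays at the moment-noise scale", {
  net <- networkParams(matrix(0, 10, 10), b = rep(-2, 10))
  r <- simulateGLM(net, nBins = 1e5, seed = 16)
  st <- exactMoments(r)
  fit <- fitMAP(st, lambda = 2e-4, warn = FALSE)
  # local sensitivity at W = 0: dSigma1/dW ~ m(1-m) * m(1-m) per entry, so a
  # moment fluctuation of size |Sigma1| maps to a weight of that size over
  # the squared Bernoulli variance
  noiseScale <- max(abs(momentCov(st, 1)[row(diag(10)) != col(diag(10))]))
  v <- momentMean(st) * (1 - momentMean(st))
  What <- estimatedWeights(fit)
  expect_lt(max(abs(What[row(What) != col(What)])),
            5 * noiseScale / min(v)^2)
})

test_that("weights are recovered accurately at full observation", {
  net <- makeTestNet(N = 20, seed = 17)
  r <- simulateGLM(net, nBins = 5e5, seed = 18)
  st <- exactMoments(r)
  W <- weightMatrix(net)
  off <- row(W) != col(W)
  sel <- selectLambda(st, targetSparsity = mean(W[off] != 0), warn = FALSE)
  C <- qualityMetrics(W, estimatedWeights(sel$result))@C
  expect_gte(C, 0.9)
})

test_that("nonzero fraction decreases along the lambda path (LASSO property)", {
  net <- makeTestNet(N = 12, seed = 19)
  r <- simulateGLM(net, nBins = 1e5, seed = 20)
  st <- exactMoments(r)
  lamGrid <- exp(seq(log(1e-5), log(5e-3), length.out = 10))
  dens <- sapply(lamGrid, function(l) {
    W <- estimatedWeights(fitMAP(st, lambda = l, warn = FALSE))
    mean(W[row(W) != col(W)] != 0)
  })
  expect_true(all(diff(dens) <= 0.01))
})

test_that("selectLambda matches a sparsity target and handles the edge cases", {
  net <- makeTestNet(N = 15, seed = 21)
  r <- simulateGLM(net, nBins = 2e5, seed = 22)
  st <- exactMoments(r)
  W <- weightMatrix(net)
  off <- row(W) != col(W)
  target <- mean(W[off] != 0)
  sel <- selectLambda(st, targetSparsity = target, warn = FALSE)
  expect_true(sel$matched)
  expect_lte(abs(sel$achievedSparsity - target), 0.02 * target + 1e-9)

  z <- selectLambda(st, targetSparsity = 0, warn = FALSE)
  Wz <- estimatedWeights(z$result)
  expect_true(all(Wz[row(Wz) != col(Wz)] == 0))
})

test_that("profile ELL is concave along random segments", {
  net <- makeTestNet(N = 6, seed = 23)
  r <- simulateGLM(net, nBins = 3e4, seed = 24)
  st <- exactMoments(r)
  set.seed(25)
  for (k in 1:20) {
    W1 <- matrix(rnorm(36, sd = 0.6), 6, 6)
    W2 <- matrix(rnorm(36, sd = 0.6), 6, 6)
    f <- function(a) profileELL(a * W1 + (1 - a) * W2, st, warn = FALSE)
    mid <- f(0.5)
    expect_gte(mid, 0.5 * f(0) + 0.5 * f(1) - 1e-8 * abs(mid))
  }
})

test_that("the fit consumes only moment statistics, never the raster", {
  net <- makeTestNet(N = 8, seed = 26)
  r <- simulateGLM(net, nBins = 5e4, seed = 27)
  st <- exactMoments(r)
  rm(r)
  fit1 <- fitMAP(st, lambda = 1e-4, warn = FALSE)
  # the claimed experiment length scales the loglikelihood but cannot change
  # the optimizer's path on the same statistics
  st2 <- st; st2@nTime <- 10L * st@nTime
  fit2 <- fitMAP(st2, lambda = 1e-4, warn = FALSE)
  expect_equal(estimatedWeights(fit1), estimatedWeights(fit2))
})

test_that("stimulus augmentation recovers gains and leaves W unchanged", {
  # (a) null stimulus: augmented fit matches unaugmented, G ~ 0
  net <- makeTestNet(N = 8, seed = 28)
  Tn <- 2e5
  r <- simulateGLM(net, nBins = Tn, seed = 29)
  X <- matrix(rnorm(Tn), 1)
  aug <- augmentStimulus(r, NULL, X)
  expect_equal(nrow(spikes(aug$raster)), 9)
  stA <- estimateMoments(aug$raster, aug$mask)
  expect_equal(momentMean(stA)[9], mean(X), tolerance = 1e-10)
  st <- exactMoments(r)
  fitP <- fitMAP(st, lambda = 3e-4, tol = 1e-12, warn = FALSE)
  fitA <- fitMAP(stA, lambda = 3e-4, tol = 1e-12, warn = FALSE)
  blocks <- splitAugmentedFit(fitA, 8, 1)
  # synaptic (off-diagonal) weights agree tightly; the weakly identified
  # refractory diagonal is allowed solver-scale slack
  dW <- abs(blocks$What - estimatedWeights(fitP))
  expect_lt(max(dW[row(dW) != col(dW)]), 0.02)
  expect_lt(max(diag(dW)), 0.3)
  expect_lt(max(abs(blocks$Ghat)), 0.1)
  # stimulus rows excluded from fitting
  expect_true(all(estimatedWeights(fitA)[9, ] == 0))

  # (b) a real step stimulus with known gains: signs recovered
  cfgS <- networkConfig(N = 10, nStimulus = 1, seed = 30)
  netS <- generateNetwork(cfgS)
  XS <- matrix(rep(c(0, 1), each = 500, length.out = Tn), 1)
  rS <- simulateGLM(netS, nBins = Tn, stimulus = XS, seed = 31)
  augS <- augmentStimulus(rS, NULL, XS)
  stS <- estimateMoments(augS$raster, augS$mask)
  fitS <- fitMAP(stS, lambda = 1e-4, warn = FALSE)
  Ghat <- splitAugmentedFit(fitS, 10, 1)$Ghat
  Gtrue <- stimulusGain(netS)
  strong <- abs(Gtrue) > 0.5
  expect_true(all(sign(Ghat[strong]) == sign(Gtrue[strong])))
})

test_that("the objective-mode FISTA trace never increases", {
  net <- makeTestNet(N = 10, seed = 31)
  r <- simulateGLM(net, nBins = 5e4, seed = 32)
  st <- exactMoments(r)
  fit <- fitMAP(st, lambda = 2e-4, gradMode = "objective", warn = FALSE)
  tr <- fit@objTrace
  expect_true(all(diff(tr) <= 1e-10 * pmax(1, abs(tr[-1]))))
})

test_that("never-observed moments warn and constrain the matching weights", {
  set.seed(33)
  S <- matrix(rbinom(900, 1, 0.3), 3, 300)
  O <- matrix(1L, 3, 300); O[3, ] <- 0L
  msk <- new("ObservationMask", O = O, scheme = "custom", pObsTarget = 2 / 3)
  st <- estimateMoments(spikeRaster(S), msk)
  expect_warning(profileELL(matrix(0, 3, 3), st), "never observed")
  fit <- suppressWarnings(fitMAP(st, lambda = 1e-4, rows = 1:2))
  expect_true(all(estimatedWeights(fit)[1:2, 3] == 0))
  expect_true(all(fit@constrained[1:2, 3]))
})
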
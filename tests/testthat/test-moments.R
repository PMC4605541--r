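test_that("degenerate and handcrafted rasters give exact moments", {
  z <- spikeRaster(matrix(0L, 3, 10))
  st <- exactMoments(z)
  expect_equal(momentMean(st), rep(0, 3))
  expect_true(all(momentCov(st, 0) == 0))
  expect_true(all(momentCov(st, 1) == 0))

  # alternating single row: oracle by direct summation of the pattern
  Tn <- 1000
  s <- rep(c(1L, 0L), Tn / 2)
  st1 <- exactMoments(spikeRaster(matrix(s, 1)))
  m <- mean(s)
  sig0 <- mean(s * s) - m^2
  sig1 <- sum(s[-1] * s[-Tn]) / (Tn - 1) - m^2
  expect_equal(momentMean(st1), m)           # 0.5
  expect_equal(momentCov(st1, 0)[1, 1], sig0)  # 0.25
  expect_equal(momentCov(st1, 1)[1, 1], sig1)  # -0.25
})

test_that("diag(Sigma0) equals m(1-m) exactly for binary data", {
  net <- makeTestNet(N = 6, seed = 3)
  r <- simulateGLM(net, nBins = 5000, seed = 4)
  st <- exactMoments(r)
  m <- momentMean(st)
  expect_equal(diag(momentCov(st, 0)), m * (1 - m))
})

test_that("masked mean renormalizes by the observation count", {
  r <- spikeRaster(matrix(c(1L, 0L, 1L, 1L), 1))
  o <- new("ObservationMask", O = matrix(c(1L, 1L, 0L, 1L), 1),
           scheme = "custom", pObsTarget = 0.75)
  expect_equal(momentMean(estimateMoments(r, o)), 2 / 3)
})

test_that("a full mask reproduces exact moments bitwise", {
  net <- makeTestNet(N = 5, seed = 6)
  r <- simulateGLM(net, nBins = 3000, seed = 7)
  ones <- new("ObservationMask", O = matrix(1L, 5, 3000), scheme = "custom",
              pObsTarget = 1)
  a <- exactMoments(r); b <- estimateMoments(r, ones)
  expect_identical(momentMean(a), momentMean(b))
  expect_identical(momentCov(a, 0), momentCov(b, 0))
  expect_identical(momentCov(a, 1), momentCov(b, 1))
})

test_that("never-observed entries are flagged NA, not zeroed", {
  S <- matrix(rbinom(40, 1, 0.4), 2, 20)
  O <- rbind(rep(1L, 20), rep(0L, 20))  # neuron 2 never observed
  r <- spikeRaster(S)
  o <- new("ObservationMask", O = O, scheme = "custom", pObsTarget = 0.5)
  st <- estimateMoments(r, o)
  expect_true(is.na(momentMean(st)[2]))
  expect_true(is.na(momentCov(st, 1)[2, 1]))
  expect_equal(momentCounts(st, "pairs1")[2, 2], 0)
  expect_false(anyNA(momentCov(st, 1)[1, 1]))
})

test_that("lag-0 statistics are invariant under joint time permutation", {
  set.seed(8)
  S <- matrix(rbinom(200, 1, 0.3), 4, 50)
  O <- matrix(rbinom(200, 1, 0.7), 4, 50)
  perm <- sample(50)
  a <- estimateMoments(spikeRaster(S), new("ObservationMask", O = O,
       scheme = "custom", pObsTarget = 0.7))
  b <- estimateMoments(spikeRaster(S[, perm]), new("ObservationMask",
       O = O[, perm], scheme = "custom", pObsTarget = 0.7))
  expect_equal(momentMean(a), momentMean(b))
  expect_equal(momentCov(a, 0), momentCov(b, 0))
})

test_that("streaming accumulation equals whole-matrix computation", {
  net <- makeTestNet(N = 8, seed = 9)
  r <- simulateGLM(net, nBins = 12345, seed = 10)
  m <- makeMask("fully_random", N = 8, nBins = 12345, pObs = 0.6, seed = 11)
  whole <- estimateMoments(r, m, chunkBins = 2e5)
  for (chunk in c(1000L, 7777L)) {
    part <- estimateMoments(r, m, chunkBins = chunk)
    expect_equal(momentMean(part), momentMean(whole), tolerance = 1e-10)
    expect_equal(momentCov(part, 0), momentCov(whole, 0), tolerance = 1e-10)
    expect_equal(momentCov(part, 1), momentCov(whole, 1), tolerance = 1e-10)
    expect_identical(momentCounts(part, "pairs1"),
                     momentCounts(whole, "pairs1"))
  }
})

test_that("masked moment estimates are consistent as T grows", {
  net <- makeTestNet(N = 10, seed = 12)
  errByT <- sapply(c(1e4, 1e5, 4e5), function(Tn) {
    errs <- sapply(1:3, function(s) {
      r <- simulateGLM(net, nBins = Tn, seed = 100 * s)
      msk <- makeMask("fully_random", N = 10, nBins = Tn, pObs = 0.3,
                      seed = 200 * s)
      st <- estimateMoments(r, msk)
      ste <- exactMoments(r)
      c(max(abs(momentMean(st) - momentMean(ste))),
        max(abs(momentCov(st, 1) - momentCov(ste, 1))))
    })
    rowMeans(errs)
  })
  # both error curves shrink stochastically toward 0
  expect_lt(errByT[1, 3], errByT[1, 1])
  expect_lt(errByT[2, 3], errByT[2, 1])
})

test_that("moment preconditions are enforced", {
  expect_error(exactMoments(spikeRaster(matrix(1L, 2, 1))), "2 time bins")
})
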
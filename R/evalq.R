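#' @include AllClasses.R ell.R netsim.R observer.R
NULL

#' Quality metrics comparing estimated and true connectivity
#'
#' Four scalar scores over all matrix entries: \code{S}, the fraction of
#' truly nonzero weights whose estimated sign matches the true sign;
#' \code{Z}, the fraction of truly zero weights estimated exactly zero;
#' \code{C}, the Pearson correlation; and \code{R2 = 1 - ||West - Wtrue||_F^2
#' / ||Wtrue - mean(Wtrue)||_F^2}. Also tabulates the detection rate (sign
#' agreement, counting 0 as a sign) as a function of the true weight value.
#'
#' @param Wtrue,West matrices of identical shape.
#' @param nBinsDetect number of weight bins for the detection table.
#' @return A \code{\link{QualityReport}}.
#' @examples
#' W <- matrix(c(0, 1, -1, 0), 2)
#' qualityMetrics(W, W)  # perfect scores
#' @export
qualityMetrics <- function(Wtrue, West, nBinsDetect = 20L) {
  stopifnot(all(dim(Wtrue) == dim(West)))
  wt <- as.numeric(Wtrue); we <- as.numeric(West)
  nz <- wt != 0
  S <- if (any(nz)) mean(sign(we[nz]) == sign(wt[nz])) else NA_real_
  Z <- if (any(!nz)) mean(we[!nz] == 0) else NA_real_
  C <- if (stats::sd(wt) > 0 && stats::sd(we) > 0) stats::cor(wt, we)
       else NA_real_
  denom <- sum((wt - mean(wt))^2)
  R2 <- if (denom > 0) 1 - sum((we - wt)^2) / denom else NA_real_
  det <- if (any(nz)) {
    br <- seq(min(wt[nz]), max(wt[nz]), length.out = nBinsDetect + 1L)
    bin <- cut(wt[nz], breaks = br, include.lowest = TRUE)
    data.frame(bin = levels(bin),
               midpoint = (br[-1] + br[-length(br)]) / 2,
               n = as.integer(table(bin)),
               detected = as.numeric(tapply(sign(we[nz]) == sign(wt[nz]),
                                            bin, mean)))
  } else data.frame()
  qualityReport(S = S, Z = Z, C = C, R2 = R2, detection = det)
}

#' Signed-detection ROC curves along the regularization path
#'
#' Sweeps the L1 weight over \code{lambdaGrid} and, for each fit, scores the
#' detection of excitatory (resp. inhibitory) connections: an off-diagonal
#' entry counts as detected when it is inferred nonzero with the right sign.
#' True positives are drawn from the truly positive (negative) entries,
#' false positives from the truly zero entries. The area under each curve is
#' computed by the trapezoid rule with the endpoints (0,0) and (1,1)
#' appended.
#'
#' @param Wtrue true weights.
#' @param stats moment statistics to fit from.
#' @param lambdaGrid numeric vector of L1 weights (>= 1 values).
#' @param nT time bins (defaults to the moment pass length).
#' @param ... passed to \code{\link{fitMAP}}.
#' @return List with \code{curves} (data.frame: lambda, class, tpr, fpr) and
#'   \code{aucE}, \code{aucI} (NA when a class is absent from the truth).
#' @export
rocBySign <- function(Wtrue, stats, lambdaGrid, nT = NULL, ...) {
  stopifnot(length(lambdaGrid) >= 1)
  N <- nrow(Wtrue)
  off <- row(Wtrue) != col(Wtrue)
  wt <- Wtrue[off]
  posE <- wt > 0; posI <- wt < 0; neg <- wt == 0
  rows <- list()
  W0 <- NULL
  for (lam in sort(lambdaGrid, decreasing = TRUE)) {
    fit <- fitMAP(stats, lambda = lam, nT = nT, W0 = W0, warn = FALSE, ...)
    W0 <- fit@What
    we <- fit@What[off]
    rows[[length(rows) + 1L]] <- data.frame(
      lambda = lam,
      tprE = if (any(posE)) mean(we[posE] > 0) else NA_real_,
      fprE = if (any(neg)) mean(we[neg] > 0) else NA_real_,
      tprI = if (any(posI)) mean(we[posI] < 0) else NA_real_,
      fprI = if (any(neg)) mean(we[neg] < 0) else NA_real_)
  }
  cur <- do.call(rbind, rows)
  aucOf <- function(fpr, tpr) {
    if (anyNA(fpr) || anyNA(tpr)) return(NA_real_)
    o <- order(fpr, tpr)
    x <- c(0, fpr[o], 1); y <- c(0, tpr[o], 1)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  list(curves = cur,
       aucE = aucOf(cur$fprE, cur$tprE),
       aucI = aucOf(cur$fprI, cur$tprI))
}

#' Common-input demonstration
#'
#' Builds a worst-case common-input network: the first \code{nBlock} neurons
#' share no connections with each other (their block of the weight matrix is
#' diagonal) but receive abundant common input from the remaining neurons.
#' Two equal-budget observation conditions are compared: (a) observing only
#' the \code{nBlock} neurons all the time (fixed subset), fitting them as if
#' the rest of the network did not exist, and (b) "shotgun" random-block
#' observation of the whole network at \code{p_obs = nBlock / N}. Both use
#' the maximum-likelihood fit (\code{lambda = 0}). Spurious off-diagonal
#' weights inside the structurally diagonal block measure the common-input
#' bias, which persists under (a) but not (b).
#'
#' @param N,nBlock network size and size of the connection-free block.
#' @param nBins experiment length in bins.
#' @param seed master seed.
#' @param pHidden connection probability from hidden neurons into the block
#'   (dense, to create many shared-input motifs).
#' @param dwell dwell time of the random-blocks scheme.
#' @param biasMean,biasSd Gaussian bias parameters (all neurons).
#' @return List with the per-condition mean absolute off-diagonal estimates
#'   inside the block (\code{fixedBias}, \code{shotgunBias}), their ratio,
#'   the two fits, and the true network.
#' @export
commonInputExperiment <- function(N = 50L, nBlock = 16L, nBins = 1e6,
                                  seed = 1L, pHidden = 0.4, dwell = 100L,
                                  biasMean = -0.5, biasSd = 0.1) {
  set.seed(seed)
  nHidden <- N - nBlock
  W <- matrix(0, N, N)
  # hidden -> block common-input motifs (Dale's law across hidden columns)
  hiddenSign <- ifelse(stats::runif(nHidden) < 0.5, 1, -1)
  for (j in seq_len(nHidden)) {
    targets <- which(stats::runif(nBlock) < pHidden)
    W[targets, nBlock + j] <- hiddenSign[j] *
      stats::rlnorm(length(targets), log(0.6), 0.4)
  }
  # recurrent connectivity among hidden neurons
  for (j in seq_len(nHidden)) {
    targets <- which(stats::runif(nHidden) < 0.2)
    W[nBlock + targets, nBlock + j] <- hiddenSign[j] *
      stats::rlnorm(length(targets), log(0.6), 0.4)
  }
  diag(W) <- -1
  b <- stats::rnorm(N, biasMean, biasSd)
  net <- networkParams(W, b)

  raster <- simulateGLM(net, nBins = nBins, seed = childSeed(seed, 1))
  blockIdx <- seq_len(nBlock)

  # (a) fixed subset: the block is fully observed, the rest never
  statsFix <- subsetMoments(exactMoments(raster), blockIdx)
  fitFix <- fitMAP(statsFix, lambda = 0, warn = FALSE)

  # (b) shotgun: random blocks over the whole network, equal budget
  maskSh <- makeMask("random_blocks", N = N, nBins = nBins,
                     pObs = nBlock / N, dwell = dwell,
                     seed = childSeed(seed, 2))
  statsSh <- estimateMoments(raster, maskSh)
  fitSh <- fitMAP(statsSh, lambda = 0, warn = FALSE)

  offBlock <- row(diag(nBlock)) != col(diag(nBlock))
  fixedBias <- mean(abs(fitFix@What[offBlock]))
  shotgunBias <- mean(abs(fitSh@What[blockIdx, blockIdx][offBlock]))
  list(fixedBias = fixedBias, shotgunBias = shotgunBias,
       ratio = fixedBias / shotgunBias,
       fitFixed = fitFix, fitShotgun = fitSh, network = net)
}

#' Full simulate-observe-fit-score recovery experiment
#'
#' The quantitative benchmark protocol: generate a network, simulate the
#' GLM, apply an observation scheme, estimate moments ignoring missing data,
#' fit the L1 MAP with the regularization matched to the true sparsity, and
#' score the estimate against the truth.
#'
#' @param N network size.
#' @param nBins experiment length in bins (default 5.5 hours of 10 ms bins).
#' @param pObs observation fraction.
#' @param scheme observation scheme (see \code{\link{makeMask}}).
#' @param seed master seed (drives network, simulation and mask).
#' @param cfg optional \code{\link{networkConfig}} overriding the default.
#' @param matchSparsity match lambda to the true off-diagonal nonzero
#'   fraction (default); otherwise fit at \code{lambda}.
#' @param lambda L1 weight when not sparsity-matching.
#' @param gradMode gradient mode for the fit.
#' @param ... further arguments to \code{\link{makeMask}}.
#' @return List with the \code{\link{QualityReport}} (\code{quality}), the
#'   number of sign errors among true nonzero weights (\code{signErrors};
#'   a zero estimate counts as an error), the count of true nonzero weights,
#'   the fit, the true network, and the lambda used.
#' @export
recoveryExperiment <- function(N = 50L, nBins = 1980000L, pObs = 0.04,
                               scheme = "double_serial", seed = 1L,
                               cfg = NULL, matchSparsity = TRUE, lambda = 0,
                               gradMode = "adjusted", ...) {
  if (is.null(cfg)) cfg <- networkConfig(N = N, seed = childSeed(seed, 1))
  net <- generateNetwork(cfg)
  raster <- simulateGLM(net, nBins = nBins, seed = childSeed(seed, 2))
  mask <- if (pObs >= 1) NULL
          else makeMask(scheme, N = N, nBins = nBins, pObs = pObs,
                        seed = childSeed(seed, 3), ...)
  stats <- estimateMoments(raster, mask)
  Wtrue <- weightMatrix(net)
  off <- row(Wtrue) != col(Wtrue)
  if (matchSparsity) {
    sel <- selectLambda(stats, targetSparsity = mean(Wtrue[off] != 0),
                        gradMode = gradMode, warn = FALSE)
    fit <- sel$result; lambdaUsed <- sel$lambda
  } else {
    fit <- fitMAP(stats, lambda = lambda, gradMode = gradMode, warn = FALSE)
    lambdaUsed <- lambda
  }
  West <- estimatedWeights(fit)
  nz <- Wtrue != 0
  # a sign error is a nonzero estimate with the opposite sign; weak weights
  # shrunk exactly to zero are counted by the Z / S scores instead
  signErrors <- sum(West[nz] != 0 & sign(West[nz]) != sign(Wtrue[nz]))
  list(quality = qualityMetrics(Wtrue, West), signErrors = signErrors,
       nNonzero = sum(nz), fit = fit, network = net, lambda = lambdaUsed)
}

#' Parameter scan of recovery quality
#'
#' Runs \code{\link{recoveryExperiment}} over a grid of conditions and
#' returns a long-format table of correlation scores. The grid may vary any
#' of \code{N}, \code{pObs}, \code{nBins}, \code{pConn}, \code{biasShift}
#' (added to both class bias means, to move the firing rate) and
#' \code{seed}; missing columns take the defaults.
#'
#' @param grid data.frame of conditions (possibly empty).
#' @param scheme observation scheme.
#' @param ... passed to \code{\link{recoveryExperiment}}.
#' @return The grid with columns \code{C}, \code{S}, \code{Z}, \code{R2}
#'   appended (empty grid in, empty table out).
#' @export
scalingScan <- function(grid, scheme = "double_serial", ...) {
  stopifnot(is.data.frame(grid))
  out <- cbind(grid, C = numeric(nrow(grid)), S = numeric(nrow(grid)),
               Z = numeric(nrow(grid)), R2 = numeric(nrow(grid)))
  if (nrow(grid) == 0) return(out)
  getcol <- function(nm, default)
    if (nm %in% names(grid)) grid[[nm]] else rep(default, nrow(grid))
  Ns <- getcol("N", 50L); ps <- getcol("pObs", 0.2)
  Ts <- getcol("nBins", 1e5); pc <- getcol("pConn", 0.163)
  bs <- getcol("biasShift", 0); sd <- getcol("seed", 1L)
  for (r in seq_len(nrow(grid))) {
    cfg <- networkConfig(N = Ns[r], pConn = pc[r],
                         seed = childSeed(sd[r], 1))
    cfg$biasMeanExc <- cfg$biasMeanExc + bs[r]
    cfg$biasMeanInh <- cfg$biasMeanInh + bs[r]
    res <- recoveryExperiment(N = Ns[r], nBins = Ts[r], pObs = ps[r],
                              scheme = scheme, seed = sd[r], cfg = cfg, ...)
    q <- res$quality
    out$C[r] <- q@C; out$S[r] <- q@S; out$Z[r] <- q@Z; out$R2[r] <- q@R2
  }
  out
}

#' Inferring the inputs of a single, always-observed neuron
#'
#' When only one output neuron's afferents are of interest, its row of the
#' weight matrix can be fitted in isolation (the profile loglikelihood
#' decomposes over rows) and the output neuron can be kept in every
#' observation bin, which raises the lag-1 pair counts for its row from
#' \code{T p_obs^2} to \code{T p_obs}.
#'
#' @param nInputs number of input neurons (the output neuron is appended).
#' @param pObs observation fraction of the inputs.
#' @param nBins experiment length.
#' @param seed master seed.
#' @param cfg optional \code{\link{networkConfig}} for the full network.
#' @param matchSparsity,lambda regularization control as in
#'   \code{\link{recoveryExperiment}}.
#' @return List with the row-restricted \code{\link{QualityReport}}, the
#'   fitted input row \code{rowHat}, the true row, the mean lag-1 pair count
#'   of the output row, and the fit.
#' @export
singleNeuronExperiment <- function(nInputs = 100L, pObs = 0.1, nBins = 2e5,
                                   seed = 1L, cfg = NULL,
                                   matchSparsity = TRUE, lambda = 0) {
  N <- nInputs + 1L
  if (is.null(cfg)) cfg <- networkConfig(N = N, seed = childSeed(seed, 1))
  net <- generateNetwork(cfg)
  raster <- simulateGLM(net, nBins = nBins, seed = childSeed(seed, 2))
  base <- makeMask("fully_random", N = N, nBins = nBins, pObs = pObs,
                   seed = childSeed(seed, 3))
  O <- maskMatrix(base)
  O[N, ] <- 1L  # always observe the output neuron
  mask <- new("ObservationMask", O = O, scheme = "custom", pObsTarget = pObs)
  stats <- estimateMoments(raster, mask)
  Wtrue <- weightMatrix(net)
  rowTrue <- Wtrue[N, , drop = FALSE]
  if (matchSparsity) {
    target <- mean(rowTrue[, -N] != 0)
    sel <- selectLambda(stats, targetSparsity = target, rows = N, warn = FALSE)
    fit <- sel$result
  } else {
    fit <- fitMAP(stats, lambda = lambda, rows = N, warn = FALSE)
  }
  rowHat <- estimatedWeights(fit)[N, , drop = FALSE]
  list(quality = qualityMetrics(rowTrue, rowHat),
       rowHat = rowHat, rowTrue = rowTrue,
       meanPairCount = mean(momentCounts(stats, "pairs1")[N, -N]),
       fit = fit)
}
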
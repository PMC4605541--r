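#' @include AllClasses.R netsim.R evalq.R
NULL

#' Configuration of the calcium-fluorescence forward model
#'
#' Autoregressive GCaMP6f-like indicator: per neuron the calcium state obeys
#' \code{c_t = d c_{t-1} + s_t} with \code{d = exp(-binWidth / decayTime)},
#' and the recorded trace is
#' \code{F_t = baseline + amplitude * c_t + eps_t}. The noise parameter
#' \code{snr} follows imaging convention in this literature: the noise
#' standard deviation is \code{snr * amplitude}, so larger \code{snr} means a
#' noisier trace (0.2 is low noise, 0.4 high noise).
#'
#' @param decayTime indicator decay time constant in seconds.
#' @param amplitude fluorescence jump per spike (arbitrary units).
#' @param baseline additive offset.
#' @param snr noise scale: noise sd = \code{snr * amplitude}.
#' @param binWidth bin width in seconds.
#' @return List of class \code{"FluorConfig"}.
#' @export
fluorConfig <- function(decayTime = 0.4, amplitude = 1, baseline = 0,
                        snr = 0.2, binWidth = 0.01) {
  if (decayTime <= 0) stop("decayTime must be positive")
  if (amplitude <= 0) stop("amplitude must be positive")
  if (snr < 0) stop("snr must be nonnegative")
  structure(list(decayTime = decayTime, amplitude = amplitude,
                 baseline = baseline, snr = snr, binWidth = binWidth,
                 decayFactor = exp(-binWidth / decayTime)),
            class = "FluorConfig")
}

#' Simulate fluorescence traces from a spike raster
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param cfg a \code{\link{fluorConfig}}.
#' @param seed RNG seed for the additive noise.
#' @return \code{N x T} matrix of fluorescence values (the forward model is
#'   linear in the spikes at \code{snr = 0}).
#' @export
simulateFluorescence <- function(raster, cfg = fluorConfig(), seed = 1L) {
  stopifnot(is(raster, "SpikeRaster"), inherits(cfg, "FluorConfig"))
  S <- raster@S
  storage.mode(S) <- "double"
  d <- cfg$decayFactor
  Fm <- t(apply(S, 1, function(s) stats::filter(s, d, method = "recursive")))
  if (nrow(S) == 1L) Fm <- matrix(Fm, 1)
  Fm <- cfg$baseline + cfg$amplitude * Fm
  if (cfg$snr > 0) {
    set.seed(seed)
    Fm <- Fm + matrix(stats::rnorm(length(Fm), sd = cfg$snr * cfg$amplitude),
                      nrow(Fm))
  }
  Fm
}

#' Infer spikes from fluorescence by matched-kernel deconvolution
#'
#' Nonnegative AR(1) deconvolution against the known indicator kernel
#' (pool-adjacent-violators active-set sweep), followed by thresholding the
#' innovations at half the unit-spike response. Deterministic, no training;
#' on noiseless traces isolated spikes are recovered exactly.
#'
#' @param traces \code{N x T} fluorescence matrix.
#' @param cfg the \code{\link{fluorConfig}} used to generate the traces.
#' @param threshold spike threshold as a fraction of the unit response.
#' @param penalty L1 penalty on innovations passed to the deconvolution
#'   (default scales with the noise level).
#' @return A binary \code{\link{SpikeRaster}}.
#' @export
inferSpikes <- function(traces, cfg = fluorConfig(), threshold = 0.5,
                        penalty = NULL) {
  traces <- as.matrix(traces)
  d <- cfg$decayFactor
  if (is.null(penalty)) penalty <- cfg$snr * cfg$amplitude
  S <- matrix(0L, nrow(traces), ncol(traces))
  for (i in seq_len(nrow(traces))) {
    y <- (traces[i, ] - cfg$baseline) / cfg$amplitude
    ci <- oasis_ar1_cpp(y, d, penalty / cfg$amplitude)
    s <- ci - d * c(0, ci[-length(ci)])
    S[i, ] <- as.integer(s >= threshold)
  }
  spikeRaster(S, binWidth = cfg$binWidth)
}

#' End-to-end fluorescence-based connectivity inference
#'
#' Simulates a network, renders fluorescence traces, infers spikes back by
#' deconvolution, applies the observation scheme, and fits connectivity
#' from the inferred spikes alongside a true-spike control.
#'
#' @param N,nBins,pObs,scheme,seed experiment settings (as in
#'   \code{\link{recoveryExperiment}}).
#' @param netCfg optional \code{\link{networkConfig}}.
#' @param fluorCfg a \code{\link{fluorConfig}}.
#' @param ... passed to \code{\link{makeMask}}.
#' @return List with quality reports for the inferred-spike and true-spike
#'   fits, the spike-inference correlation, mean firing rates, and both fits.
#' @export
fluorescencePipeline <- function(N = 50L, nBins = 2e5, pObs = 1,
                                 scheme = "random_blocks", seed = 1L,
                                 netCfg = NULL, fluorCfg = fluorConfig(),
                                 ...) {
  if (is.null(netCfg)) netCfg <- networkConfig(N = N, seed = childSeed(seed, 1))
  net <- generateNetwork(netCfg)
  raster <- simulateGLM(net, nBins = nBins, seed = childSeed(seed, 2),
                        binWidth = fluorCfg$binWidth)
  traces <- simulateFluorescence(raster, fluorCfg, seed = childSeed(seed, 3))
  inferred <- inferSpikes(traces, fluorCfg)
  mask <- if (pObs >= 1) NULL
          else makeMask(scheme, N = N, nBins = nBins, pObs = pObs,
                        seed = childSeed(seed, 4), ...)
  Wtrue <- weightMatrix(net)
  off <- row(Wtrue) != col(Wtrue)
  target <- mean(Wtrue[off] != 0)
  fitOne <- function(r) {
    stats <- estimateMoments(r, mask)
    selectLambda(stats, targetSparsity = target, warn = FALSE)$result
  }
  fitTrue <- fitOne(raster)
  fitInf <- fitOne(inferred)
  spikeCor <- stats::cor(as.numeric(spikes(raster)),
                         as.numeric(spikes(inferred)))
  list(qualityInferred = qualityMetrics(Wtrue, estimatedWeights(fitInf)),
       qualityTrue = qualityMetrics(Wtrue, estimatedWeights(fitTrue)),
       spikeCorrelation = spikeCor,
       meanRateHz = mean(spikes(raster)) / fluorCfg$binWidth,
       fitInferred = fitInf, fitTrue = fitTrue, network = net)
}

#' Correlation between two rasters after re-binning
#'
#' Bins both rasters at a coarser width and reports the mean over neurons of
#' the per-neuron Pearson correlation; the standard score for comparing
#' deconvolved spikes with the ground truth at various temporal precisions.
#'
#' @param rasterA,rasterB equal-shape \code{\link{SpikeRaster}}s.
#' @param binFactor number of original bins per coarse bin.
#' @return Mean per-neuron correlation (neurons with zero variance skipped).
#' @export
binnedSpikeCorrelation <- function(rasterA, rasterB, binFactor = 1L) {
  A <- spikes(rasterA); B <- spikes(rasterB)
  stopifnot(all(dim(A) == dim(B)))
  if (binFactor > 1L) {
    Tn <- (ncol(A) %/% binFactor) * binFactor
    idx <- rep(seq_len(Tn %/% binFactor), each = binFactor)
    A <- t(apply(A[, seq_len(Tn), drop = FALSE], 1,
                 function(s) tapply(s, idx, sum)))
    B <- t(apply(B[, seq_len(Tn), drop = FALSE], 1,
                 function(s) tapply(s, idx, sum)))
  }
  cors <- vapply(seq_len(nrow(A)), function(i) {
    if (stats::sd(A[i, ]) == 0 || stats::sd(B[i, ]) == 0) NA_real_
    else stats::cor(A[i, ], B[i, ])
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}
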
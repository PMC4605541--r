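#' @include AllClasses.R
NULL

#' Configuration for the random network generator
#'
#' Describes a sparse, Dale's-law-respecting cortical-like network. Each
#' presynaptic neuron is either excitatory or inhibitory; every off-diagonal
#' weight is nonzero independently with probability \code{pConn}. Excitatory
#' magnitudes are log-normal (right-skewed: most weights weak, a few strong);
#' inhibitory magnitudes use the same shape scaled by \code{inhScale}, so
#' inhibitory synapses are typically stronger. Diagonal entries are a fixed
#' negative self-weight modelling post-spike refractoriness. Biases are
#' Gaussian per class; inhibitory neurons get a higher bias so they fire
#' roughly twice as fast as excitatory ones. The defaults are tuned so that
#' a 50-neuron network with 10 ms bins fires near 3 Hz.
#'
#' @param N number of neurons.
#' @param pConn off-diagonal connection probability in (0, 1].
#' @param fracInhibitory fraction of inhibitory neurons in [0, 1].
#' @param excMeanLog,excSdLog log-normal parameters of excitatory magnitudes.
#' @param inhScale multiplicative scale of inhibitory vs excitatory magnitudes.
#' @param diagWeight fixed (negative) self-weight.
#' @param biasMeanExc,biasMeanInh,biasSd Gaussian bias parameters per class.
#' @param nStimulus number of external stimulus channels (columns of G).
#' @param stimGainSd standard deviation of Gaussian stimulus gains.
#' @param seed integer RNG seed; the same config and seed always produce the
#'   identical network.
#' @return A validated list of class \code{"NetworkGenConfig"}.
#' @export
networkConfig <- function(N = 50L, pConn = 0.163, fracInhibitory = 0.2,
                          excMeanLog = log(0.178), excSdLog = 0.6,
                          inhScale = 3, diagWeight = -3,
                          biasMeanExc = -3.6, biasMeanInh = -2.9,
                          biasSd = 0.15, nStimulus = 0L, stimGainSd = 1,
                          seed = 1L) {
  if (pConn <= 0 || pConn > 1) stop("pConn must be in (0, 1]")
  if (fracInhibitory < 0 || fracInhibitory > 1)
    stop("fracInhibitory must be in [0, 1]")
  if (N < 1) stop("N must be positive")
  cfg <- list(N = as.integer(N), pConn = pConn,
              fracInhibitory = fracInhibitory,
              excMeanLog = excMeanLog, excSdLog = excSdLog,
              inhScale = inhScale, diagWeight = diagWeight,
              biasMeanExc = biasMeanExc, biasMeanInh = biasMeanInh,
              biasSd = biasSd, nStimulus = as.integer(nStimulus),
              stimGainSd = stimGainSd, seed = as.integer(seed))
  class(cfg) <- "NetworkGenConfig"
  cfg
}

#' Generate a ground-truth network
#'
#' Draws a \code{\link{NetworkParams}} realization from a
#' \code{\link{networkConfig}}: sparse Dale's-law connectivity with
#' log-normal excitatory and (stronger) inhibitory weights, fixed negative
#' diagonal, and Gaussian biases.
#'
#' @param cfg a \code{\link{networkConfig}}.
#' @return A \code{\link{NetworkParams}}.
#' @examples
#' net <- generateNetwork(networkConfig(N = 20, seed = 7))
#' mean(weightMatrix(net)[row(diag(20)) != col(diag(20))] != 0)  # ~ pConn
#' @export
generateNetwork <- function(cfg) {
  stopifnot(inherits(cfg, "NetworkGenConfig"))
  set.seed(cfg$seed)
  N <- cfg$N
  nInh <- round(cfg$fracInhibitory * N)
  inhib <- rep(FALSE, N)
  if (nInh > 0) inhib[sample.int(N, nInh)] <- TRUE

  conn <- matrix(stats::runif(N * N) < cfg$pConn, N, N)
  diag(conn) <- FALSE
  mag <- matrix(stats::rlnorm(N * N, meanlog = cfg$excMeanLog,
                              sdlog = cfg$excSdLog), N, N)
  W <- matrix(0, N, N)
  sgn <- ifelse(inhib[col(W)], -cfg$inhScale, 1)
  W[conn] <- (mag * sgn)[conn]
  diag(W) <- cfg$diagWeight

  b <- stats::rnorm(N, mean = ifelse(inhib, cfg$biasMeanInh, cfg$biasMeanExc),
                    sd = cfg$biasSd)
  G <- if (cfg$nStimulus > 0)
    matrix(stats::rnorm(N * cfg$nStimulus, sd = cfg$stimGainSd), N, cfg$nStimulus)
  else matrix(0, N, 0)
  p <- networkParams(W, b, G)
  attr(p, "inhibitory") <- inhib
  p
}

#' Simulate spiking activity under the logistic GLM
#'
#' Runs the discrete-time network: \code{U[,t] = W S[,t-1] + b + G X[,t]} and
#' \code{S[i,t] ~ Bernoulli(logistic(U[i,t]))}, independently across neurons
#' given the input. The initial state is all-zeros followed by \code{burnIn}
#' discarded bins (stimulus is applied only to the retained bins).
#'
#' @param params a \code{\link{NetworkParams}}.
#' @param nBins number of retained time bins (\code{T >= 1}).
#' @param stimulus optional \code{D x T} stimulus matrix (required iff
#'   \code{params} has stimulus channels).
#' @param seed integer RNG seed; identical inputs give bitwise-identical rasters.
#' @param binWidth bin width in seconds (bookkeeping only; the dynamics are
#'   per-bin). Default 10 ms.
#' @param burnIn discarded initial bins.
#' @return A \code{\link{SpikeRaster}}.
#' @examples
#' net <- generateNetwork(networkConfig(N = 10, seed = 1))
#' r <- simulateGLM(net, nBins = 1000, seed = 2)
#' mean(spikes(r)) / binWidth(r)  # ~ 3 Hz
#' @export
simulateGLM <- function(params, nBins, stimulus = NULL, seed = 1L,
                        binWidth = 0.01, burnIn = 1000L) {
  stopifnot(is(params, "NetworkParams"), nBins >= 1)
  N <- nNeurons(params)
  D <- ncol(params@G)
  GX <- matrix(0, N, 0)
  if (D > 0) {
    if (is.null(stimulus)) stop("params has stimulus gain; stimulus required")
    stimulus <- as.matrix(stimulus)
    if (nrow(stimulus) != D || ncol(stimulus) != nBins)
      stop("stimulus must be D x nBins")
    GX <- params@G %*% stimulus
  } else if (!is.null(stimulus)) {
    stop("stimulus given but params has no stimulus gain")
  }
  set.seed(seed)
  out <- simulate_glm_cpp(params@W, params@b, GX, as.integer(nBins),
                          as.integer(burnIn), integer(N))
  spikeRaster(out$S, binWidth = binWidth, s0 = out$s0)
}

#' Configuration of the leaky integrate-and-fire simulator
#'
#' @param tauM membrane integration timescale in seconds; the per-bin decay
#'   factor is \code{gamma = exp(-binWidth / tauM)}.
#' @param noiseSd standard deviation of the per-bin Gaussian membrane noise.
#' @param threshold spike threshold on the membrane potential.
#' @param binWidth bin width in seconds.
#' @return A list of class \code{"LIFConfig"} (with \code{gamma} resolved).
#' @export
lifConfig <- function(tauM = 0.02, noiseSd = 1, threshold = 0.5,
                      binWidth = 0.01) {
  gamma <- exp(-binWidth / tauM)
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  structure(list(gamma = gamma, noiseSd = noiseSd, threshold = threshold,
                 binWidth = binWidth), class = "LIFConfig")
}

#' Simulate spiking activity under a stochastic LIF model
#'
#' Mismatched neuron model used to probe robustness of the GLM-based
#' inference. Membrane update per bin:
#' \code{V[i,t] = (gamma V[i,t-1] + (1-gamma) U[i,t] + eps[i,t]) * I(S[i,t] == 0)}
#' with \code{S[i,t] = I(V[i,t-1] > threshold)} and \code{U} as in the GLM.
#' The potential is reset in the bin of the spike, giving one bin of
#' absolute refractoriness.
#'
#' @inheritParams simulateGLM
#' @param cfg a \code{\link{lifConfig}}.
#' @return A \code{\link{SpikeRaster}}.
#' @export
simulateLIF <- function(params, nBins, cfg = lifConfig(), stimulus = NULL,
                        seed = 1L, burnIn = 1000L) {
  stopifnot(is(params, "NetworkParams"), nBins >= 1, inherits(cfg, "LIFConfig"))
  N <- nNeurons(params)
  D <- ncol(params@G)
  GX <- matrix(0, N, 0)
  if (D > 0) {
    if (is.null(stimulus)) stop("params has stimulus gain; stimulus required")
    stimulus <- as.matrix(stimulus)
    if (nrow(stimulus) != D || ncol(stimulus) != nBins)
      stop("stimulus must be D x nBins")
    GX <- params@G %*% stimulus
  }
  set.seed(seed)
  out <- simulate_lif_cpp(params@W, params@b, GX, as.integer(nBins),
                          as.integer(burnIn), cfg$gamma, cfg$noiseSd,
                          cfg$threshold)
  spikeRaster(out$S, binWidth = cfg$binWidth, s0 = out$s0)
}
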
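#' @import methods
NULL

#' Ground-truth generative parameters of a spiking network
#'
#' Container for the parameters of the logistic GLM network model: the
#' \code{N x N} connectivity matrix \code{W} (entry \code{[i, j]} is the
#' weight from presynaptic neuron \code{j} to postsynaptic neuron \code{i};
#' the diagonal holds post-spike self-effects such as refractoriness), the
#' bias vector \code{b} controlling baseline firing rates, and an optional
#' \code{N x D} stimulus gain \code{G}.
#'
#' @slot W numeric \code{N x N} weight matrix.
#' @slot b numeric length-\code{N} bias vector.
#' @slot G numeric \code{N x D} stimulus gain (zero columns when no stimulus).
#' @export
setClass("NetworkParams",
         slots = c(W = "matrix", b = "numeric", G = "matrix"))

setValidity("NetworkParams", function(object) {
  N <- length(object@b)
  if (!all(dim(object@W) == c(N, N))) return("W must be N x N with N = length(b)")
  if (!all(is.finite(object@W))) return("W must be finite")
  if (!all(is.finite(object@b))) return("b must be finite")
  if (nrow(object@G) != N) return("G must have N rows")
  if (ncol(object@G) > 0 && !all(is.finite(object@G))) return("G must be finite")
  TRUE
})

#' @param W,b,G see slots.
#' @rdname NetworkParams-class
#' @export
networkParams <- function(W, b, G = NULL) {
  W <- as.matrix(W)
  if (is.null(G)) G <- matrix(0, nrow = length(b), ncol = 0)
  new("NetworkParams", W = W, b = as.numeric(b), G = as.matrix(G))
}

#' Binary spike raster
#'
#' An \code{N x T} matrix of 0/1 spike indicators, one row per neuron and one
#' column per time bin, together with the bin width (seconds) and the network
#' state \code{s0} in the bin preceding the first column (needed because the
#' GLM input at bin \code{t} depends on the spikes at \code{t - 1}). When a
#' stimulus has been appended as pseudo-neurons (see
#' \code{\link{augmentStimulus}}), the last \code{nStim} rows are real-valued.
#'
#' @slot S numeric/integer \code{N x T} matrix.
#' @slot binWidth bin width in seconds.
#' @slot s0 state preceding the first bin.
#' @slot nStim number of trailing real-valued stimulus rows (0 for plain rasters).
#' @export
setClass("SpikeRaster",
         slots = c(S = "matrix", binWidth = "numeric", s0 = "numeric",
                   nStim = "integer"))

setValidity("SpikeRaster", function(object) {
  N <- nrow(object@S)
  if (ncol(object@S) < 1) return("raster needs at least one time bin")
  if (length(object@s0) != N) return("s0 must have one entry per row")
  if (object@binWidth <= 0) return("binWidth must be positive")
  nSpk <- N - object@nStim
  if (nSpk > 0) {
    sub <- object@S[seq_len(nSpk), , drop = FALSE]
    r <- range(sub)
    if (r[1] < 0 || r[2] > 1) return("spike entries must be in {0, 1}")
    if (length(sub) <= 1e6 && any(sub != floor(sub)))
      return("spike entries must be integral")
  }
  TRUE
})

#' @param S,binWidth,s0,nStim see slots.
#' @rdname SpikeRaster-class
#' @export
spikeRaster <- function(S, binWidth = 0.01, s0 = NULL, nStim = 0L) {
  S <- as.matrix(S)
  if (is.null(s0)) s0 <- numeric(nrow(S))
  new("SpikeRaster", S = S, binWidth = binWidth, s0 = as.numeric(s0),
      nStim = as.integer(nStim))
}

#' Observation mask
#'
#' Binary \code{N x T} matrix marking which neuron/bin entries were recorded
#' (\code{O[i, t] = 1} when the spike \code{S[i, t]} is available), plus the
#' sampling scheme that generated it and its target observation fraction.
#'
#' @slot O binary \code{N x T} matrix.
#' @slot scheme one of \code{"fixed"}, \code{"serial"}, \code{"fully_random"},
#'   \code{"random_blocks"}, \code{"double_serial"}, or \code{"custom"}.
#' @slot pObsTarget requested mean fraction of neurons observed per bin.
#' @export
setClass("ObservationMask",
         slots = c(O = "matrix", scheme = "character", pObsTarget = "numeric"))

setValidity("ObservationMask", function(object) {
  r <- range(object@O)
  if (r[1] < 0 || r[2] > 1) return("mask entries must be in {0, 1}")
  if (object@pObsTarget <= 0 || object@pObsTarget > 1)
    return("pObsTarget must be in (0, 1]")
  TRUE
})

#' Approximate sufficient statistics of a (partially observed) raster
#'
#' The first and second spike moments that the expected-loglikelihood fit
#' consumes: per-neuron mean spike probabilities \code{m}, the lag-0
#' covariance \code{Sigma0}, and the lag-1 covariance \code{Sigma1} (entry
#' \code{[i, j]} pairs neuron \code{i} at bin \code{t} with neuron \code{j}
#' at bin \code{t - 1}). Per-entry observation counts are retained so that
#' entries never jointly observed can be flagged (they are \code{NA} in the
#' moment slots) rather than silently fabricated.
#'
#' @slot m length-\code{N} mean spike probabilities (\code{NA} if never observed).
#' @slot Sigma0,Sigma1 \code{N x N} covariances (\code{NA} where unidentified).
#' @slot countsM per-neuron observation counts.
#' @slot counts0,counts1 per-entry joint observation counts.
#' @slot nTime number of time bins the statistics were accumulated over.
#' @slot binWidth bin width in seconds.
#' @slot nStim number of trailing stimulus rows (their \code{m} is a time
#'   average of the stimulus, not a probability).
#' @export
setClass("MomentStats",
         slots = c(m = "numeric", Sigma0 = "matrix", Sigma1 = "matrix",
                   countsM = "numeric", counts0 = "matrix", counts1 = "matrix",
                   nTime = "integer", binWidth = "numeric", nStim = "integer"))

setValidity("MomentStats", function(object) {
  N <- length(object@m)
  for (nm in c("Sigma0", "Sigma1", "counts0", "counts1"))
    if (!all(dim(slot(object, nm)) == c(N, N)))
      return(sprintf("%s must be N x N", nm))
  nSpk <- N - object@nStim
  msub <- object@m[seq_len(nSpk)]
  if (any(msub < 0 | msub > 1, na.rm = TRUE))
    return("m must lie in [0, 1] for spike rows")
  if (any(object@countsM < 0) || any(object@counts0 < 0) || any(object@counts1 < 0))
    return("counts must be nonnegative")
  s0 <- object@Sigma0
  s0[is.na(s0)] <- 0
  if (max(abs(s0 - t(s0))) > 1e-8 * (1 + max(abs(s0))))
    return("Sigma0 must be symmetric")
  TRUE
})

#' Result of a connectivity fit
#'
#' @slot What estimated weight matrix.
#' @slot bHat recovered biases (profile maximizers).
#' @slot lambda L1 regularization weight used.
#' @slot objTrace penalized objective value per iteration (minimization scale).
#' @slot iterations iterations run.
#' @slot converged whether the relative-change tolerance was met.
#' @slot constrained logical matrix of entries held at zero because their
#'   moment statistics were never observed.
#' @export
setClass("InferenceResult",
         slots = c(What = "matrix", bHat = "numeric", lambda = "numeric",
                   objTrace = "numeric", iterations = "integer",
                   converged = "logical", constrained = "matrix"))

setValidity("InferenceResult", function(object) {
  if (!all(is.finite(object@What))) return("What must be finite")
  TRUE
})

#' Estimation quality summary
#'
#' Scalar scores comparing an estimated weight matrix to the truth:
#' sign-detection rate \code{S}, zero-detection rate \code{Z}, Pearson
#' correlation \code{C}, coefficient of determination \code{R2}, optional
#' per-class areas under the ROC curve for excitatory/inhibitory detection,
#' and a detection-rate-by-weight table.
#'
#' @slot S,Z,C,R2,aucE,aucI numeric scalars (\code{NA} when undefined).
#' @slot detection data.frame with weight-bin detection rates.
#' @export
setClass("QualityReport",
         slots = c(S = "numeric", Z = "numeric", C = "numeric", R2 = "numeric",
                   aucE = "numeric", aucI = "numeric", detection = "data.frame"))

# internal constructor (slot "C" would partially match new()'s Class argument)
qualityReport <- function(S, Z, C, R2, aucE = NA_real_, aucI = NA_real_,
                          detection = data.frame()) {
  x <- new("QualityReport")
  x@S <- S; x@Z <- Z; x@C <- C; x@R2 <- R2
  x@aucE <- aucE; x@aucI <- aucI; x@detection <- detection
  validObject(x)
  x
}
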
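#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \code{weightMatrix} and \code{biases} for \code{NetworkParams},
#' \code{spikes}/\code{binWidth}/\code{initialState} for \code{SpikeRaster},
#' \code{maskMatrix}/\code{scheme}/\code{pObsEmpirical} for
#' \code{ObservationMask}, \code{momentMean}/\code{momentCov} for
#' \code{MomentStats}, and \code{estimatedWeights}/\code{estimatedBiases}
#' for \code{InferenceResult}.
#'
#' @param x object.
#' @param lag for \code{momentCov}, 0 or 1.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setMethod("weightMatrix", "NetworkParams", function(x) x@W)

#' @rdname accessors
#' @export
setGeneric("biases", function(x) standardGeneric("biases"))
#' @rdname accessors
#' @export
setMethod("biases", "NetworkParams", function(x) x@b)

#' @rdname accessors
#' @export
setGeneric("stimulusGain", function(x) standardGeneric("stimulusGain"))
#' @rdname accessors
#' @export
setMethod("stimulusGain", "NetworkParams", function(x) x@G)

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setMethod("nNeurons", "NetworkParams", function(x) length(x@b))
#' @rdname accessors
#' @export
setMethod("nNeurons", "SpikeRaster", function(x) nrow(x@S) - x@nStim)
#' @rdname accessors
#' @export
setMethod("nNeurons", "ObservationMask", function(x) nrow(x@O))

#' @rdname accessors
#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
#' @rdname accessors
#' @export
setMethod("spikes", "SpikeRaster", function(x) x@S)

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setMethod("binWidth", "SpikeRaster", function(x) x@binWidth)
#' @rdname accessors
#' @export
setMethod("binWidth", "MomentStats", function(x) x@binWidth)

#' @rdname accessors
#' @export
setGeneric("initialState", function(x) standardGeneric("initialState"))
#' @rdname accessors
#' @export
setMethod("initialState", "SpikeRaster", function(x) x@s0)

#' @rdname accessors
#' @export
setGeneric("nTimeBins", function(x) standardGeneric("nTimeBins"))
#' @rdname accessors
#' @export
setMethod("nTimeBins", "SpikeRaster", function(x) ncol(x@S))
#' @rdname accessors
#' @export
setMethod("nTimeBins", "ObservationMask", function(x) ncol(x@O))
#' @rdname accessors
#' @export
setMethod("nTimeBins", "MomentStats", function(x) as.integer(x@nTime))

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "ObservationMask", function(x) x@O)

#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname accessors
#' @export
setMethod("scheme", "ObservationMask", function(x) x@scheme)

#' @rdname accessors
#' @export
setGeneric("pObsEmpirical", function(x) standardGeneric("pObsEmpirical"))
#' @rdname accessors
#' @export
setMethod("pObsEmpirical", "ObservationMask", function(x) mean(x@O))

#' @rdname accessors
#' @export
setGeneric("momentMean", function(x) standardGeneric("momentMean"))
#' @rdname accessors
#' @export
setMethod("momentMean", "MomentStats", function(x) x@m)

#' @rdname accessors
#' @export
setGeneric("momentCov", function(x, lag = 0L) standardGeneric("momentCov"))
#' @rdname accessors
#' @export
setMethod("momentCov", "MomentStats", function(x, lag = 0L) {
  stopifnot(lag %in% c(0L, 1L))
  if (lag == 0L) x@Sigma0 else x@Sigma1
})

#' @rdname accessors
#' @export
setGeneric("momentCounts", function(x, which = "pairs1") standardGeneric("momentCounts"))
#' @rdname accessors
#' @param which \code{"mean"}, \code{"pairs0"}, or \code{"pairs1"}.
#' @export
setMethod("momentCounts", "MomentStats", function(x, which = "pairs1") {
  switch(match.arg(which, c("mean", "pairs0", "pairs1")),
         mean = x@countsM, pairs0 = x@counts0, pairs1 = x@counts1)
})

#' @rdname accessors
#' @export
setGeneric("estimatedWeights", function(x) standardGeneric("estimatedWeights"))
#' @rdname accessors
#' @export
setMethod("estimatedWeights", "InferenceResult", function(x) x@What)

#' @rdname accessors
#' @export
setGeneric("estimatedBiases", function(x) standardGeneric("estimatedBiases"))
#' @rdname accessors
#' @export
setMethod("estimatedBiases", "InferenceResult", function(x) x@bHat)

setMethod("show", "NetworkParams", function(object) {
  N <- length(object@b)
  dens <- mean(object@W[row(object@W) != col(object@W)] != 0)
  cat(sprintf("NetworkParams: %d neurons, off-diagonal density %.3f, %d stimulus channel(s)\n",
              N, dens, ncol(object@G)))
})

setMethod("show", "SpikeRaster", function(object) {
  N <- nrow(object@S) - object@nStim
  cat(sprintf("SpikeRaster: %d neurons x %d bins (%.0f ms bins)%s\n",
              N, ncol(object@S), 1000 * object@binWidth,
              if (object@nStim > 0) sprintf(" + %d stimulus row(s)", object@nStim) else ""))
  rate <- mean(object@S[seq_len(N), ]) / object@binWidth
  cat(sprintf("  mean firing rate %.2f Hz\n", rate))
})

setMethod("show", "ObservationMask", function(object) {
  cat(sprintf("ObservationMask: scheme '%s', %d x %d, p_obs target %.3f / empirical %.3f\n",
              object@scheme, nrow(object@O), ncol(object@O),
              object@pObsTarget, mean(object@O)))
})

setMethod("show", "MomentStats", function(object) {
  nz <- sum(object@counts1 == 0)
  cat(sprintf("MomentStats: %d neurons over %d bins; %d lag-1 pair(s) never observed\n",
              length(object@m), object@nTime, nz))
})

setMethod("show", "InferenceResult", function(object) {
  cat(sprintf("InferenceResult: %d x %d weights, lambda = %.3g, %d iterations (%s)\n",
              nrow(object@What), ncol(object@What), object@lambda,
              object@iterations,
              if (isTRUE(object@converged)) "converged" else "not converged"))
  cat(sprintf("  off-diagonal nonzero fraction %.3f\n",
              mean(object@What[row(object@What) != col(object@What)] != 0)))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: S = %.3f, Z = %.3f, C = %.3f, R2 = %.3f\n",
              object@S, object@Z, object@C, object@R2))
  if (isTRUE(!is.na(object@aucE)) || isTRUE(!is.na(object@aucI)))
    cat(sprintf("  AUC excitatory %.3f, inhibitory %.3f\n", object@aucE, object@aucI))
})
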
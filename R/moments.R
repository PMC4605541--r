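#' @include AllClasses.R
NULL

# ---- streaming accumulation -------------------------------------------------
#
# The moment estimators are plain re-normalized empirical sums:
#   m[i]         = sum_t O[i,t] S[i,t]                / sum_t O[i,t]
#   Sigma0[i,j]  = sum_t O O S S (lag 0)  / counts0   - m[i] m[j]
#   Sigma1[i,j]  = sum_{t>=2} O O S S (lag 1) / counts1 - m[i] m[j]
# accumulated over time chunks so rasters longer than memory can be streamed.
# Entries whose joint-observation count is zero are NA (flagged, never 0).

#' Create an empty moment accumulator
#'
#' One-pass accumulation interface: feed time chunks of the raster and the
#' mask with \code{\link{accumulateMoments}} and close with
#' \code{\link{finalizeMoments}}. Chunk boundaries only affect floating-point
#' summation order.
#'
#' @param N number of rows (neurons plus any stimulus rows).
#' @return An accumulator environment.
#' @export
momentAccumulator <- function(N) {
  acc <- new.env(parent = emptyenv())
  acc$N <- as.integer(N)
  acc$sumO <- numeric(N); acc$sumOS <- numeric(N)
  acc$n0 <- matrix(0, N, N); acc$c0 <- matrix(0, N, N)
  acc$n1 <- matrix(0, N, N); acc$c1 <- matrix(0, N, N)
  acc$prevA <- NULL; acc$prevO <- NULL
  acc$nTime <- 0L
  acc
}

#' Feed one time chunk into a moment accumulator
#'
#' @param acc accumulator from \code{\link{momentAccumulator}}.
#' @param S \code{N x L} spike (or augmented) chunk.
#' @param O \code{N x L} observation chunk (defaults to fully observed).
#' @return The accumulator, invisibly.
#' @export
accumulateMoments <- function(acc, S, O = NULL) {
  S <- as.matrix(S); storage.mode(S) <- "double"
  if (is.null(O)) O <- matrix(1, nrow(S), ncol(S))
  else { O <- as.matrix(O); storage.mode(O) <- "double" }
  stopifnot(nrow(S) == acc$N, all(dim(S) == dim(O)))
  A <- O * S
  L <- ncol(S)
  acc$sumO <- acc$sumO + rowSums(O)
  acc$sumOS <- acc$sumOS + rowSums(A)
  acc$n0 <- acc$n0 + tcrossprod(A)
  acc$c0 <- acc$c0 + tcrossprod(O)
  if (L > 1) {
    acc$n1 <- acc$n1 + tcrossprod(A[, 2:L, drop = FALSE], A[, 1:(L - 1), drop = FALSE])
    acc$c1 <- acc$c1 + tcrossprod(O[, 2:L, drop = FALSE], O[, 1:(L - 1), drop = FALSE])
  }
  if (!is.null(acc$prevA)) {
    acc$n1 <- acc$n1 + tcrossprod(A[, 1], acc$prevA)
    acc$c1 <- acc$c1 + tcrossprod(O[, 1], acc$prevO)
  }
  acc$prevA <- A[, L]; acc$prevO <- O[, L]
  acc$nTime <- acc$nTime + L
  invisible(acc)
}

#' Close a moment accumulator
#'
#' @param acc accumulator with at least 2 bins accumulated.
#' @param binWidth bin width in seconds (metadata).
#' @param nStim number of trailing stimulus rows (metadata).
#' @return A \code{\link{MomentStats}}.
#' @export
finalizeMoments <- function(acc, binWidth = 0.01, nStim = 0L) {
  if (acc$nTime < 2L) stop("need at least 2 time bins for lag-1 moments")
  m <- ifelse(acc$sumO > 0, acc$sumOS / acc$sumO, NA_real_)
  mm <- tcrossprod(m)
  Sigma0 <- ifelse(acc$c0 > 0, acc$n0 / acc$c0, NA_real_) - mm
  Sigma1 <- ifelse(acc$c1 > 0, acc$n1 / acc$c1, NA_real_) - mm
  new("MomentStats", m = m, Sigma0 = Sigma0, Sigma1 = Sigma1,
      countsM = acc$sumO, counts0 = acc$c0, counts1 = acc$c1,
      nTime = as.integer(acc$nTime), binWidth = binWidth,
      nStim = as.integer(nStim))
}

#' Estimate moments from a partially observed raster
#'
#' Computes the approximate sufficient statistics of the
#' expected-loglikelihood fit by ignoring unobserved entries and
#' re-normalizing the empirical sums by per-entry observation counts.
#' Lag-1 averages run over \code{t = 2..T} (no wraparound). Entries whose
#' joint count is zero are returned as \code{NA} with their zero count
#' recorded; downstream code decides the policy (the ELL fit zeroes them and
#' constrains the matching weights). With a fully observed mask the result
#' equals \code{\link{exactMoments}} bitwise.
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param mask an \code{\link{ObservationMask}} or \code{NULL} (fully observed).
#' @param chunkBins chunk length for the streaming pass.
#' @return A \code{\link{MomentStats}}.
#' @examples
#' r <- spikeRaster(matrix(c(1, 0, 1, 1), 1))
#' o <- new("ObservationMask", O = matrix(c(1L, 1L, 0L, 1L), 1),
#'          scheme = "custom", pObsTarget = 0.75)
#' momentMean(estimateMoments(r, o))  # (1 + 0 + 1) / 3
#' @export
estimateMoments <- function(raster, mask = NULL, chunkBins = 100000L) {
  stopifnot(is(raster, "SpikeRaster"))
  S <- raster@S
  Tn <- ncol(S)
  O <- if (is.null(mask)) NULL else {
    stopifnot(is(mask, "ObservationMask"), all(dim(mask@O) == dim(S)))
    mask@O
  }
  acc <- momentAccumulator(nrow(S))
  for (start in seq(1L, Tn, by = chunkBins)) {
    end <- min(start + chunkBins - 1L, Tn)
    accumulateMoments(acc, S[, start:end, drop = FALSE],
                      if (is.null(O)) NULL else O[, start:end, drop = FALSE])
  }
  finalizeMoments(acc, binWidth = raster@binWidth, nStim = raster@nStim)
}

#' Exact moments of a fully observed raster
#'
#' @param raster a \code{\link{SpikeRaster}} with at least 2 bins.
#' @return A \code{\link{MomentStats}}; identical to
#'   \code{\link{estimateMoments}} with an all-ones mask.
#' @export
exactMoments <- function(raster) {
  if (ncol(raster@S) < 2) stop("need at least 2 time bins for lag-1 moments")
  estimateMoments(raster, mask = NULL)
}

# Subset a MomentStats to a set of rows/columns (used when fitting an
# observed sub-network as if the rest of the network did not exist).
subsetMoments <- function(stats, idx) {
  new("MomentStats", m = stats@m[idx],
      Sigma0 = stats@Sigma0[idx, idx, drop = FALSE],
      Sigma1 = stats@Sigma1[idx, idx, drop = FALSE],
      countsM = stats@countsM[idx],
      counts0 = stats@counts0[idx, idx, drop = FALSE],
      counts1 = stats@counts1[idx, idx, drop = FALSE],
      nTime = stats@nTime, binWidth = stats@binWidth, nStim = 0L)
}
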
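#' @include AllClasses.R
NULL

#' Generate an observation mask
#'
#' Builds the binary \code{N x T} observation matrix for one of five
#' sampling schemes, all observing (approximately) \code{pObs * N} neurons
#' per bin:
#' \describe{
#'   \item{fixed}{the same \code{k = ceiling(pObs N)} neurons (rows
#'     \code{1..k}) in every bin; the rest are never observed.}
#'   \item{serial}{a contiguous block of \code{k} neurons advancing
#'     cyclically one position every \code{dwell} bins (with wraparound);
#'     pairs further apart than the block are never co-observed.}
#'   \item{fully_random}{i.i.d. Bernoulli(\code{pObs}) entries.}
#'   \item{random_blocks}{a uniformly random subset of size \code{k},
#'     redrawn every \code{dwell} bins and held constant within the dwell.}
#'   \item{double_serial}{the union of two serial scanners with blocks of
#'     size \code{k/2} (rounded) and dwell times \code{dwellA}, \code{dwellB}
#'     bins per position. With coprime dwell times the relative phase of the
#'     two scanners drifts through all combinations, so every neuron pair is
#'     eventually co-observed.}
#' }
#'
#' @param scheme one of \code{"fixed"}, \code{"serial"}, \code{"fully_random"},
#'   \code{"random_blocks"}, \code{"double_serial"}.
#' @param N,nBins mask dimensions.
#' @param pObs target mean fraction of neurons observed per bin;
#'   \code{pObs * N >= 1} is required.
#' @param dwell bins per scanner position (serial, random_blocks).
#' @param dwellA,dwellB dwell times of the two scanners (double_serial);
#'   coprime values guarantee full pair coverage.
#' @param seed RNG seed for the stochastic schemes.
#' @return An \code{\link{ObservationMask}}.
#' @examples
#' m <- makeMask("fully_random", N = 20, nBins = 1000, pObs = 0.3, seed = 1)
#' pObsEmpirical(m)
#' @export
makeMask <- function(scheme = c("fixed", "serial", "fully_random",
                                "random_blocks", "double_serial"),
                     N, nBins, pObs, dwell = 50L, dwellA = 13L, dwellB = 17L,
                     seed = 1L) {
  scheme <- match.arg(scheme)
  N <- as.integer(N); nBins <- as.integer(nBins)
  if (nBins < 1) stop("nBins must be >= 1")
  if (pObs * N < 1) stop("pObs * N must be at least 1")
  k <- as.integer(ceiling(pObs * N))
  O <- matrix(0L, N, nBins)
  if (scheme == "fixed") {
    O[seq_len(k), ] <- 1L
  } else if (scheme == "serial") {
    pos <- (floor((seq_len(nBins) - 1) / dwell)) %% N
    for (j in seq_len(k) - 1L)
      O[cbind(((pos + j) %% N) + 1L, seq_len(nBins))] <- 1L
  } else if (scheme == "fully_random") {
    set.seed(seed)
    O[] <- as.integer(stats::runif(N * nBins) < pObs)
  } else if (scheme == "random_blocks") {
    set.seed(seed)
    nBlocks <- ceiling(nBins / dwell)
    for (bk in seq_len(nBlocks)) {
      rows <- sample.int(N, k)
      cols <- ((bk - 1L) * dwell + 1L):min(bk * dwell, nBins)
      O[rows, cols] <- 1L
    }
  } else { # double_serial
    kA <- max(1L, as.integer(floor(k / 2)))
    kB <- max(1L, k - kA)
    t <- seq_len(nBins) - 1L
    # Scanner A cycles through N positions (cycle N * dwellA bins). Scanner B
    # pauses one extra dwell per sweep, giving it N + 1 phases and a cycle of
    # (N + 1) * dwellB bins. When the two cycle lengths are coprime the joint
    # phase pattern sweeps every (position A, position B) combination within
    # one super-period (Chinese remainder theorem), so every neuron pair is
    # eventually co-observed.
    posA <- floor(t / dwellA) %% N
    phaseB <- floor(t / dwellB) %% (N + 1L)
    posB <- (ifelse(phaseB == N, 0L, phaseB) + floor(N / 2)) %% N
    cycA <- N * dwellA; cycB <- (N + 1L) * dwellB
    g <- cycA; h <- cycB
    while (h != 0) { tmp <- g %% h; g <- h; h <- tmp }
    if (g != 1L)
      warning(sprintf(paste0("double_serial cycle lengths %d and %d share ",
                             "factor %d; some pairs may never be co-observed"),
                      cycA, cycB, g), call. = FALSE)
    cols <- seq_len(nBins)
    for (j in seq_len(kA) - 1L) O[cbind(((posA + j) %% N) + 1L, cols)] <- 1L
    for (j in seq_len(kB) - 1L) O[cbind(((posB + j) %% N) + 1L, cols)] <- 1L
  }
  new("ObservationMask", O = O, scheme = scheme, pObsTarget = pObs)
}

#' Empirical pair-coverage frequency of a mask
#'
#' Entry \code{[i, j]} is the fraction of (valid) bins in which neuron
#' \code{i} was observed at time \code{t} jointly with neuron \code{j} at
#' time \code{t - lag}. These frequencies determine which covariance entries
#' are identifiable from the masked data.
#'
#' @param mask an \code{\link{ObservationMask}}.
#' @param lag 0 or 1.
#' @return An \code{N x N} matrix of frequencies in [0, 1].
#' @export
pairCoverage <- function(mask, lag = 0L) {
  stopifnot(is(mask, "ObservationMask"), lag %in% c(0L, 1L))
  O <- mask@O
  Tn <- ncol(O)
  if (Tn <= lag) stop("need more bins than the lag")
  pairCounts(O, lag) / (Tn - lag)
}

# Chunked joint-observation counts sum_t O[i,t] * O[j,t-lag]; avoids a full
# integer-to-double copy of wide masks.
pairCounts <- function(O, lag = 0L, chunkBins = 200000L) {
  N <- nrow(O); Tn <- ncol(O)
  acc <- matrix(0, N, N)
  prev <- NULL
  for (start in seq(1L, Tn, by = chunkBins)) {
    end <- min(start + chunkBins - 1L, Tn)
    A <- O[, start:end, drop = FALSE]
    storage.mode(A) <- "double"
    if (lag == 0L) {
      acc <- acc + tcrossprod(A)
    } else {
      L <- ncol(A)
      if (L > 1)
        acc <- acc + tcrossprod(A[, 2:L, drop = FALSE], A[, 1:(L - 1), drop = FALSE])
      if (!is.null(prev)) acc <- acc + tcrossprod(A[, 1], prev)
      prev <- A[, L]
    }
  }
  acc
}

#' Identifiability diagnosis of an observation mask
#'
#' Checks the conditions under which the missing-data moment estimators
#' converge: every neuron must be observed a positive fraction of the time,
#' and every neuron pair must be jointly observed (at lag 0 and lag 1) in a
#' positive fraction of bins. Neurons and pairs with zero counts are listed;
#' the mask is \code{fullyIdentifiable} only if none exist.
#'
#' @param mask an \code{\link{ObservationMask}}.
#' @return A list with \code{fullyIdentifiable}, \code{unobservedNeurons},
#'   \code{uncoveredPairs0}, \code{uncoveredPairs1} (two-column index
#'   matrices), and the per-neuron observation fractions.
#' @export
checkIdentifiability <- function(mask) {
  stopifnot(is(mask, "ObservationMask"))
  O <- mask@O
  Tn <- ncol(O)
  neuronCounts <- rowSums(O)
  cov0 <- pairCounts(O, 0L)
  cov1 <- if (Tn > 1) pairCounts(O, 1L) else matrix(0, nrow(O), nrow(O))
  bad0 <- which(cov0 == 0, arr.ind = TRUE)
  bad1 <- which(cov1 == 0, arr.ind = TRUE)
  res <- list(fullyIdentifiable = length(bad0) == 0 && length(bad1) == 0 &&
                all(neuronCounts > 0),
              unobservedNeurons = which(neuronCounts == 0),
              uncoveredPairs0 = unname(bad0),
              uncoveredPairs1 = unname(bad1),
              neuronObsFraction = neuronCounts / Tn)
  class(res) <- "identifiabilityReport"
  res
}

#' @export
print.identifiabilityReport <- function(x, ...) {
  cat(sprintf("Identifiability: %s\n",
              if (x$fullyIdentifiable) "all moments identifiable"
              else "NOT fully identifiable"))
  if (length(x$unobservedNeurons))
    cat(sprintf("  %d neuron(s) never observed\n", length(x$unobservedNeurons)))
  if (nrow(x$uncoveredPairs0))
    cat(sprintf("  %d lag-0 pair(s) never co-observed\n", nrow(x$uncoveredPairs0)))
  if (nrow(x$uncoveredPairs1))
    cat(sprintf("  %d lag-1 pair(s) never co-observed\n", nrow(x$uncoveredPairs1)))
  invisible(x)
}
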
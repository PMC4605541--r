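#' Numerically stable logistic function
#'
#' The spiking nonlinearity of the network model: the probability that a
#' neuron spikes given its summed input \code{u} is \code{1/(1 + exp(-u))}.
#'
#' @param u Numeric vector of inputs; \code{+/-Inf} are allowed as limits.
#' @return Probabilities in \code{[0, 1]}.
#' @examples
#' logistic(0)       # 0.5
#' logistic(log(3))  # 0.75
#' @export
logistic <- function(u) {
  if (anyNA(u)) stop("logistic: NaN/NA input")
  stats::plogis(u)
}

#' Stable log(1 + exp(x))
#' @param x numeric vector
#' @return \code{log(1 + exp(x))} without overflow for large \code{x}.
#' @keywords internal
log1pexp <- function(x) {
  out <- x
  lo <- x <= 0
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + log1p(exp(-x[!lo]))
  out
}

# Bernoulli entropy in nats; 0 at m = 0 or 1.
binaryEntropy <- function(m) {
  h <- numeric(length(m))
  ok <- m > 0 & m < 1
  mm <- m[ok]
  h[ok] <- -mm * log(mm) - (1 - mm) * log1p(-mm)
  h
}

# Largest eigenvalue of a symmetric PSD-ish matrix by power iteration.
powerIterMaxEig <- function(A, iters = 100L, tol = 1e-10) {
  n <- nrow(A)
  if (n == 1L) return(abs(A[1, 1]))
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (k in seq_len(iters)) {
    w <- A %*% v
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(0)
    v <- as.numeric(w / nw)
    if (abs(nw - lam) < tol * max(1, nw)) break
    lam <- nw
  }
  nw
}

# Soft-threshold operator for the L1 proximal step.
softThreshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

# Internal: derive a child seed from a master seed (kept below 2^31).
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
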
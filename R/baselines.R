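#' @include AllClasses.R ell.R
NULL

#' Exact GLM loglikelihood of a fully observed raster
#'
#' \code{sum_i sum_t [S_it U_it - log(1 + exp(U_it))]} with
#' \code{U[,t] = W S[,t-1] + b (+ G X[,t])}; the reference quantity the
#' expected-loglikelihood approximates. Requires the full raster (it sums
#' over every bin).
#'
#' @param W,b network parameters (\code{G X} may be passed pre-multiplied via
#'   \code{stimInput}).
#' @param raster a fully observed \code{\link{SpikeRaster}}.
#' @param stimInput optional \code{N x T} matrix of stimulus drive.
#' @return Scalar loglikelihood (nats).
#' @export
fullLogLik <- function(W, b, raster, stimInput = NULL) {
  stopifnot(is(raster, "SpikeRaster"))
  S <- raster@S
  Tn <- ncol(S)
  Sprev <- cbind(raster@s0, S[, -Tn, drop = FALSE])
  U <- W %*% Sprev + b
  if (!is.null(stimInput)) U <- U + stimInput
  sum(S * U) - sum(log1pexp(U))
}

#' Standard MAP estimate from the full likelihood
#'
#' The conventional estimator the ELL method is benchmarked against: FISTA
#' on \code{-fullLogLik / T + lambda * sum |W_offdiag|}, jointly in
#' \code{(W, b)} with the biases unpenalized. Only defined for fully
#' observed rasters; with missing data use the moment-based
#' \code{\link{fitMAP}}. Each iteration touches the whole raster
#' (\code{O(N^2 T)}), which is what makes this baseline slow.
#'
#' @param raster a fully observed \code{\link{SpikeRaster}}.
#' @param lambda nonnegative L1 weight.
#' @param mask optional \code{\link{ObservationMask}}; any unobserved entry
#'   is an error directing the user to the ELL path.
#' @param penalizeDiagonal include the diagonal in the penalty.
#' @param maxIter,tol iteration cap and relative objective tolerance.
#' @return An \code{\link{InferenceResult}}.
#' @export
fitMAPFull <- function(raster, lambda = 0, mask = NULL,
                       penalizeDiagonal = FALSE, maxIter = 10000L,
                       tol = 1e-9) {
  stopifnot(is(raster, "SpikeRaster"), lambda >= 0)
  if (!is.null(mask) && any(mask@O == 0))
    stop("fitMAPFull requires a fully observed raster; ",
         "use estimateMoments() + fitMAP() for partial observations")
  S <- raster@S
  storage.mode(S) <- "double"
  N <- nrow(S); Tn <- ncol(S)
  Sprev <- cbind(raster@s0, S[, -Tn, drop = FALSE])
  # Curvature bound: Hessian <= (1/4) E[x x'] with x = (S_prev, 1). The
  # covariates are nonnegative, so the second-moment matrix is dominated by
  # the diagonal of its row sums (Gershgorin); a per-coordinate step from
  # that diagonal majorizer copes with rare spike covariates far better
  # than a single scalar step.
  X2 <- tcrossprod(Sprev) / Tn
  xb <- rowMeans(Sprev)
  M <- rbind(cbind(X2, xb), c(xb, 1))
  Lvec <- 0.25 * rowSums(M) + 1e-8
  LW <- Lvec[seq_len(N)]          # per presynaptic covariate
  Lb <- Lvec[N + 1]

  penMask <- matrix(TRUE, N, N)
  if (!penalizeDiagonal) diag(penMask) <- FALSE
  SXt <- tcrossprod(S, Sprev)          # sum_t S[,t] Sprev[,t]'
  rowS <- rowSums(S)

  negll <- function(W, b) {
    U <- W %*% Sprev + b
    (sum(log1pexp(U)) - sum(S * U)) / Tn
  }
  gradMin <- function(W, b) {
    U <- W %*% Sprev + b
    P <- stats::plogis(U)
    gW <- (P %*% t(Sprev) - SXt) / Tn
    gb <- (rowSums(P) - rowS) / Tn
    list(W = gW, b = gb)
  }

  W <- matrix(0, N, N); b <- numeric(N)
  Yw <- W; Yb <- b; th <- 1
  Fcur <- negll(W, b) + lambda * sum(abs(W[penMask]))
  trace <- numeric(0); converged <- FALSE; it <- 0L
  proxW <- function(Yw, gW)
    softThreshold(Yw - sweep(gW, 2, LW, "/"),
                  sweep(penMask * lambda, 2, LW, "/"))
  while (it < maxIter) {
    it <- it + 1L
    g <- gradMin(Yw, Yb)
    Wn <- proxW(Yw, g$W)
    bn <- Yb - g$b / Lb
    Fn <- negll(Wn, bn) + lambda * sum(abs(Wn[penMask]))
    if (Fn > Fcur + 1e-12 * max(1, abs(Fcur))) {
      th <- 1
      g <- gradMin(W, b)
      Wn <- proxW(W, g$W)
      bn <- b - g$b / Lb
      Fn <- negll(Wn, bn) + lambda * sum(abs(Wn[penMask]))
      if (Fn > Fcur + 1e-12 * max(1, abs(Fcur))) {
        LW <- LW * 2; Lb <- Lb * 2
        next
      }
    }
    thn <- (1 + sqrt(1 + 4 * th^2)) / 2
    Yw <- Wn + ((th - 1) / thn) * (Wn - W)
    Yb <- bn + ((th - 1) / thn) * (bn - b)
    relchg <- abs(Fn - Fcur) / max(abs(Fcur), 1e-12)
    W <- Wn; b <- bn; Fcur <- Fn; th <- thn
    trace <- c(trace, Fcur)
    if (relchg < tol) { converged <- TRUE; break }
  }
  new("InferenceResult", What = W, bHat = b, lambda = lambda,
      objTrace = trace, iterations = it, converged = converged,
      constrained = matrix(FALSE, N, N))
}

#' Gibbs imputation of unobserved spikes
#'
#' Single-site Gibbs sampler over the missing entries of a raster, holding
#' the supplied \code{(W, b)} fixed as the true connectivity. Missing
#' \code{S[i,t]} is resampled from its full conditional, which couples the
#' bin's own input with the likelihood of every postsynaptic neuron at
#' \code{t + 1}. Sites are scanned systematically in \code{(t, i)} order;
#' observed entries are never modified.
#'
#' @param raster \code{\link{SpikeRaster}} (missing entries may hold
#'   arbitrary placeholder values).
#' @param mask \code{\link{ObservationMask}} marking the observed entries.
#' @param W,b assumed network parameters.
#' @param sweeps number of full sweeps over the missing entries.
#' @param seed RNG seed.
#' @param init initialization of missing entries: \code{"rate"} draws
#'   i.i.d. Bernoulli at each neuron's observed rate, \code{"zero"} clears
#'   them, \code{"keep"} leaves the placeholder values.
#' @param returnSamples also return the per-sweep states of the missing
#'   entries (row = missing site in scan order, column = sweep).
#' @return The completed \code{\link{SpikeRaster}}, or (with
#'   \code{returnSamples}) a list with elements \code{raster} and
#'   \code{samples}.
#' @export
gibbsImpute <- function(raster, mask, W, b, sweeps = 31L, seed = 1L,
                        init = c("rate", "zero", "keep"),
                        returnSamples = FALSE) {
  stopifnot(is(raster, "SpikeRaster"), is(mask, "ObservationMask"),
            all(dim(raster@S) == dim(mask@O)), sweeps >= 1)
  init <- match.arg(init)
  S <- raster@S
  storage.mode(S) <- "integer"
  O <- mask@O
  storage.mode(O) <- "integer"
  set.seed(seed)
  if (init != "keep") {
    miss <- O == 0L
    if (init == "zero") S[miss] <- 0L
    else {
      obsCount <- rowSums(O)
      rate <- ifelse(obsCount > 0, rowSums(S * O) / obsCount, 0.5)
      rmat <- matrix(rate, nrow(S), ncol(S))
      S[miss] <- as.integer(stats::runif(sum(miss)) < rmat[miss])
    }
  }
  out <- gibbs_impute_cpp(S, O, as.integer(round(raster@s0)), W, b,
                          as.integer(sweeps), returnSamples)
  completed <- new("SpikeRaster", S = out$S, binWidth = raster@binWidth,
                   s0 = raster@s0, nStim = 0L)
  if (returnSamples) list(raster = completed, samples = out$samples)
  else completed
}

#' One Monte-Carlo EM step around the ELL fit
#'
#' Imputes the missing spikes by Gibbs sampling at the current estimate
#' (single retained sample after the burn-in sweeps), recomputes exact
#' moments on the completed raster, and refits the ELL MAP at the same
#' regularization. Used to test whether explicitly filling in missing data
#' improves on simply ignoring it in the moment estimators.
#'
#' @param raster,mask the observed data.
#' @param result current \code{\link{InferenceResult}} (initialization).
#' @param lambda L1 weight for the refit (defaults to the current one).
#' @param sweeps Gibbs sweeps (burn-in plus one retained sample).
#' @param seed RNG seed.
#' @param ... passed to \code{\link{fitMAP}}.
#' @return The refitted \code{\link{InferenceResult}}.
#' @export
emStep <- function(raster, mask, result, lambda = NULL, sweeps = 31L,
                   seed = 1L, ...) {
  stopifnot(is(result, "InferenceResult"))
  if (is.null(lambda)) lambda <- result@lambda
  completed <- gibbsImpute(raster, mask, result@What, result@bHat,
                           sweeps = sweeps, seed = seed, init = "rate")
  stats <- exactMoments(completed)
  fitMAP(stats, lambda = lambda, W0 = result@What, warn = FALSE, ...)
}
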
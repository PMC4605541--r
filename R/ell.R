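#' @include AllClasses.R moments.R utils.R
NULL

#' Gaussian expectation of the softplus function
#'
#' Closed-form approximation to \code{E[log(1 + exp(x))]} for
#' \code{x ~ N(mu, sigma2)}:
#' \code{sqrt(1 + pi sigma2 / 8) * log(1 + exp(mu / sqrt(1 + pi sigma2 / 8)))}.
#' This is the integral approximation at the heart of the expected
#' loglikelihood; it is accurate near the bulk of the logistic but degrades
#' for strongly negative \code{mu} (which is why an adjusted gradient mode
#' exists, see \code{\link{ellGradient}}).
#'
#' @param mu mean(s) of the Gaussian input.
#' @param sigma2 variance(s), nonnegative.
#' @return Approximate expectation(s).
#' @examples
#' gaussianSigmoidIntegral(0, 0)        # log(2)
#' gaussianSigmoidIntegral(0, 8 / pi)   # sqrt(2) * log(2)
#' @export
gaussianSigmoidIntegral <- function(mu, sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  kappa <- sqrt(1 + pi * sigma2 / 8)
  kappa * log1pexp(mu / kappa)
}

# Resolve flagged (never-observed) moment entries: NA covariances enter the
# objective as 0 and the matching weights are constrained to 0.
sanitizeMoments <- function(stats, warn = TRUE) {
  Sigma0 <- stats@Sigma0; Sigma1 <- stats@Sigma1; m <- stats@m
  bad0 <- is.na(Sigma0); bad1 <- is.na(Sigma1); badm <- is.na(m)
  nBad <- sum(bad1) + sum(badm)
  if (warn && nBad > 0)
    warning(sprintf(paste0("%d moment entr%s never observed; treated as 0 and ",
                           "the matching weights constrained to 0"),
            nBad, if (nBad == 1) "y was" else "ies were"), call. = FALSE)
  Sigma0[bad0] <- 0; Sigma1[bad1] <- 0; m[badm] <- 0
  constrained <- bad1 | outer(badm, badm, "|")
  list(m = m, Sigma0 = Sigma0, Sigma1 = Sigma1, constrained = constrained)
}

# Row quadratic forms w_i' Sigma0 w_i, clipped at zero (partial observation
# can make the plug-in Sigma0 slightly non-PSD).
rowQuadForm <- function(W, Sigma0) {
  q <- rowSums((W %*% Sigma0) * W)
  pmax(q, 0)
}

#' Profile expected loglikelihood
#'
#' The loglikelihood of the weight matrix with the biases profiled out
#' (replaced by their maximizing values), under the expected-loglikelihood
#' and Gaussian-input approximations:
#' \deqn{T \sum_i [ \sum_j W_{ij} \Sigma^{(1)}_{ij} - h(m_i)
#'       \sqrt{1 + (\pi/8) W_{i\cdot} \Sigma^{(0)} W_{i\cdot}^\top} ]}
#' with \code{h} the Bernoulli entropy. It depends on the raster only
#' through the moment statistics and decomposes over the rows of \code{W}.
#'
#' @param W weight matrix (same dimension as the moments).
#' @param stats a \code{\link{MomentStats}}.
#' @param nT number of time bins (defaults to the moment pass length).
#' @param warn warn about flagged moment entries.
#' @return Scalar profile ELL value (natural log scale).
#' @export
profileELL <- function(W, stats, nT = NULL, warn = TRUE) {
  stopifnot(is(stats, "MomentStats"))
  if (is.null(nT)) nT <- stats@nTime
  sm <- sanitizeMoments(stats, warn = warn)
  h <- binaryEntropy(sm$m)
  kappa <- sqrt(1 + (pi / 8) * rowQuadForm(W, sm$Sigma0))
  nT * (sum(W * sm$Sigma1) - sum(h * kappa))
}

#' Recover the profile-maximizing biases
#'
#' Given weights and moment statistics, the bias that maximizes the
#' approximate loglikelihood is
#' \code{b_i = kappa_i logit(m_i) - sum_k W_ik m_k}, where
#' \code{kappa_i = sqrt(1 + (pi/8) W_i. Sigma0 W_i.')}. With \code{W = 0}
#' this reduces to the independent-Bernoulli logit.
#'
#' @inheritParams profileELL
#' @return Length-\code{N} bias vector.
#' @export
recoverBias <- function(W, stats, warn = FALSE) {
  sm <- sanitizeMoments(stats, warn = warn)
  m <- sm$m
  bad <- which(m <= 0 | m >= 1)
  bad <- setdiff(bad, if (stats@nStim > 0)
    (length(m) - stats@nStim + 1):length(m) else integer(0))
  if (length(bad))
    stop(sprintf("cannot recover bias: neuron(s) %s have mean rate 0 or 1",
                 paste(bad, collapse = ", ")))
  kappa <- sqrt(1 + (pi / 8) * rowQuadForm(W, sm$Sigma0))
  lg <- ifelse(m > 0 & m < 1, log(m / (1 - m)), NA_real_)
  as.numeric(kappa * lg - W %*% m)
}

#' Gradient of the expected loglikelihood in the weights
#'
#' Two modes. \code{"objective"} is the exact analytic gradient of the
#' implemented \code{\link{profileELL}}:
#' \code{T (Sigma1 - h(m_i) (pi/8) / kappa_i * (W Sigma0))}.
#' \code{"adjusted"} differentiates the original loglikelihood first and
#' applies the expectation approximation afterwards, which is more accurate
#' where the closed-form integral is weakest (low-rate neurons):
#' \code{T (Sigma1_ij + m_i m_j - m_j sigma((mu_i + c_ij / m_j) / kappa_ij))}
#' with \code{c = W Sigma0} and the biases at their profile values (so the
#' bias stationarity \code{m_i = sigma(mu_i / kappa_i)} holds). The
#' denominator uses the variance of the input conditional on the
#' presynaptic spike: conditioning on \code{S_j = 1} fixes the direct
#' \code{W_ij} contribution, so
#' \code{kappa_ij^2 = 1 + (pi/8)(sigma_i^2 + W_ij^2 Sigma0_jj - 2 W_ij c_ij)}.
#' This conditional-variance form is what the Monte-Carlo expected-gradient
#' oracle validates. Columns with \code{m_j = 0} contribute zero.
#'
#' @inheritParams profileELL
#' @param mode \code{"objective"} or \code{"adjusted"}.
#' @return Ascent-direction gradient matrix, same shape as \code{W}.
#' @export
ellGradient <- function(W, stats, nT = NULL, mode = c("objective", "adjusted"),
                        warn = FALSE) {
  mode <- match.arg(mode)
  if (is.null(nT)) nT <- stats@nTime
  sm <- sanitizeMoments(stats, warn = warn)
  m <- sm$m
  h <- binaryEntropy(m)
  C <- W %*% sm$Sigma0
  kappa <- sqrt(1 + (pi / 8) * rowQuadForm(W, sm$Sigma0))
  if (mode == "objective") {
    G <- sm$Sigma1 - (h * (pi / 8) / kappa) * C
  } else {
    pos <- m > 0 & m < 1
    lg <- ifelse(pos, log(m / (1 - m)), 0)
    q <- rowQuadForm(W, sm$Sigma0)
    vcond <- pmax(q + sweep(W^2, 2, diag(sm$Sigma0), "*") - 2 * W * C, 0)
    kapC <- sqrt(1 + (pi / 8) * vcond)
    # arg[i, j] = (kappa_i logit(m_i) + C[i, j] / m_j) / kappa_ij
    arg <- (kappa * lg + sweep(C, 2, ifelse(m > 0, m, 1), "/")) / kapC
    sig <- stats::plogis(arg)
    G <- sm$Sigma1 + tcrossprod(m) - sweep(sig, 2, m, "*")
    G[, m == 0] <- 0
    G[!pos, ] <- 0
    if (stats@nStim > 0) {
      # real-valued stimulus columns: the binary conditioning trick does not
      # apply; by Stein's lemma E[f(U)(X - mX)] = cov(U, X) E[f'(U)], with
      # E[f'(U)] ~ m(1 - m)/kappa at the profile bias
      sc <- (length(m) - stats@nStim + 1):length(m)
      mm <- ifelse(pos, m, 0.5)
      G[, sc] <- sm$Sigma1[, sc] - C[, sc] * (mm * (1 - mm) / kappa)
      G[!pos, sc] <- 0
    }
  }
  G[sm$constrained] <- 0
  nT * G
}

#' L1-regularized MAP fit of the connectivity from moment statistics
#'
#' Minimizes \code{-profileELL(W)/T + lambda * sum |W_ij|} (off-diagonal
#' penalty by default) by FISTA: proximal gradient with Nesterov
#' acceleration, soft-thresholding proximal step, constant per-row step
#' sizes from a power-iteration bound on the curvature, and a monotone
#' restart on objective increase. The objective decomposes over rows, which
#' are updated jointly as matrix operations; each iteration costs
#' \code{O(N^3)} and never touches the raster. Flagged (never-observed)
#' moment entries keep their weights constrained to zero.
#'
#' @param stats a \code{\link{MomentStats}}.
#' @param lambda nonnegative L1 weight (per-entry scale; the objective is
#'   normalized by \code{T}).
#' @param nT number of time bins (defaults to the moment pass length).
#' @param penalizeDiagonal whether the L1 penalty also covers the diagonal
#'   (post-spike self-weights); default \code{FALSE}.
#' @param gradMode \code{"objective"} (default) or \code{"adjusted"}; see
#'   \code{\link{ellGradient}}.
#' @param rows indices of the rows of \code{W} to fit (default: all
#'   non-stimulus rows). Unfitted rows are returned as zero.
#' @param maxIter,tol iteration cap and relative objective-change tolerance.
#' @param psd \code{"clip"} clips negative row quadratic forms at zero;
#'   \code{"eigen"} projects \code{Sigma0} onto the PSD cone once up front.
#' @param W0 optional warm start.
#' @param weightBound box constraint on every weight (absolute value); keeps
#'   the adjusted-mode fixed point bounded when a noisy moment has no finite
#'   root. Generously above physiological synaptic scales by default.
#' @param warn warn about flagged moment entries.
#' @return An \code{\link{InferenceResult}}.
#' @export
fitMAP <- function(stats, lambda = 0, nT = NULL, penalizeDiagonal = FALSE,
                   gradMode = c("adjusted", "objective"), rows = NULL,
                   maxIter = 50000L, tol = 1e-9, psd = c("clip", "eigen"),
                   W0 = NULL, weightBound = 10, warn = TRUE) {
  stopifnot(is(stats, "MomentStats"), lambda >= 0)
  gradMode <- match.arg(gradMode)
  psd <- match.arg(psd)
  if (is.null(nT)) nT <- stats@nTime
  sm <- sanitizeMoments(stats, warn = warn)
  N <- length(sm$m)
  nStim <- stats@nStim
  if (is.null(rows)) rows <- seq_len(N - nStim)
  rows <- as.integer(rows)
  nr <- length(rows)

  Sigma0 <- sm$Sigma0
  if (psd == "eigen") {
    es <- eigen((Sigma0 + t(Sigma0)) / 2, symmetric = TRUE)
    Sigma0 <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
  }
  m <- sm$m
  mr <- m[rows]
  if (any(mr <= 0 | mr >= 1))
    stop(sprintf("cannot fit rows with mean rate 0 or 1 (neuron(s) %s)",
                 paste(rows[mr <= 0 | mr >= 1], collapse = ", ")))
  h <- binaryEntropy(mr)
  S1 <- sm$Sigma1[rows, , drop = FALSE]
  freeMask <- !sm$constrained[rows, , drop = FALSE]
  penMask <- matrix(TRUE, nr, N)
  if (!penalizeDiagonal) penMask[cbind(seq_len(nr), rows)] <- FALSE
  lgm <- log(mr / (1 - mr))

  eigmax <- powerIterMaxEig(Sigma0)
  L <- if (gradMode == "objective") pmax(h, 1e-8) * (pi / 8) * eigmax
       else pmax(0.25, h * (pi / 8)) * eigmax
  L <- pmax(L, 1e-8)

  # smooth part (minimization scale, per unit time): f = sum_i h_i kappa_i - <W, Sigma1>
  fval <- function(W) {
    kap <- sqrt(1 + (pi / 8) * rowQuadForm(W, Sigma0))
    sum(h * kap) - sum(W * S1)
  }
  d0 <- diag(Sigma0)
  gradMin <- function(W) {
    C <- W %*% Sigma0
    q <- rowQuadForm(W, Sigma0)
    kap <- sqrt(1 + (pi / 8) * q)
    if (gradMode == "objective") {
      (h * (pi / 8) / kap) * C - S1
    } else {
      kapC <- sqrt(1 + (pi / 8) * pmax(q + sweep(W^2, 2, d0, "*") - 2 * W * C, 0))
      arg <- (kap * lgm + sweep(C, 2, ifelse(m > 0, m, 1), "/")) / kapC
      G <- S1 + tcrossprod(mr, m) - sweep(stats::plogis(arg), 2, m, "*")
      G[, m == 0] <- 0
      if (nStim > 0) {
        sc <- (N - nStim + 1):N
        G[, sc] <- S1[, sc] - C[, sc] * (mr * (1 - mr) / kap)
      }
      -G
    }
  }
  penalty <- function(W) lambda * sum(abs(W[penMask]))
  proxStep <- function(Y, G) {
    Wn <- Y - G / L
    thr <- (lambda / L) * penMask
    Wn <- softThreshold(Wn, thr)
    # box constraint: exact prox of L1 + box. Keeps the adjusted fixed-point
    # iteration bounded when a noisy moment falls outside the range the
    # field can match (no finite root; the entry pins at the bound).
    Wn <- pmin(pmax(Wn, -weightBound), weightBound)
    Wn * freeMask
  }

  W <- if (is.null(W0)) matrix(0, nr, N) else (W0[rows, , drop = FALSE] * freeMask)
  Y <- W
  th <- 1
  Fcur <- fval(W) + penalty(W)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  if (gradMode == "objective") {
    # monotone FISTA on the (convex) penalized negative profile ELL
    while (it < maxIter) {
      it <- it + 1L
      Wn <- proxStep(Y, gradMin(Y))
      Fn <- fval(Wn) + penalty(Wn)
      if (Fn > Fcur + 1e-12 * max(1, abs(Fcur))) {
        # momentum overshoot: restart from the current iterate
        th <- 1
        Wn <- proxStep(W, gradMin(W))
        Fn <- fval(Wn) + penalty(Wn)
        if (Fn > Fcur + 1e-12 * max(1, abs(Fcur))) {
          # curvature bound too small: damp the step
          L <- L * 2
          trace <- c(trace, Fcur)
          next
        }
      }
      thn <- (1 + sqrt(1 + 4 * th^2)) / 2
      Y <- Wn + ((th - 1) / thn) * (Wn - W)
      relchg <- abs(Fn - Fcur) / max(abs(Fcur), 1e-12)
      W <- Wn; Fcur <- Fn; th <- thn
      trace <- c(trace, Fcur)
      if (!is.finite(Fcur)) stop("non-finite objective in fitMAP")
      if (relchg < tol) { converged <- TRUE; break }
    }
  } else {
    # The adjusted field is not the gradient of the implemented surrogate,
    # so run the accelerated proximal iteration to its fixed point with a
    # gradient-scheme adaptive restart and an iterate-change stopping rule.
    tolW <- max(tol, 1e-10)^0.5  # ~3e-5 relative change in W
    divergeLimit <- 1e3 * sqrt(length(W))
    damped <- FALSE
    while (it < maxIter) {
      it <- it + 1L
      Wn <- proxStep(Y, gradMin(Y))
      if (sum((Y - Wn) * (Wn - W)) > 0) {  # momentum fighting the field
        th <- 1
        Wn <- proxStep(W, gradMin(W))
      }
      if (!all(is.finite(Wn)) || sqrt(sum(Wn * Wn)) > divergeLimit) {
        # the adjusted field is only meaningful at moderate weight norms;
        # restart once from zero with a damped step, else flag
        if (!damped) {
          damped <- TRUE
          L <- L * 10
          W <- matrix(0, nr, N); Y <- W; th <- 1
          next
        }
        converged <- FALSE
        break
      }
      nrmW <- sqrt(sum(W * W))
      relchg <- sqrt(sum((Wn - W)^2)) / max(nrmW, 1e-8)
      thn <- (1 + sqrt(1 + 4 * th^2)) / 2
      Y <- Wn + ((th - 1) / thn) * (Wn - W)
      W <- Wn; th <- thn
      Fcur <- fval(W) + penalty(W)
      trace <- c(trace, Fcur)
      if (relchg < tolW) { converged <- TRUE; break }
    }
  }

  Wfull <- matrix(0, N, N)
  Wfull[rows, ] <- W
  constrainedFull <- matrix(FALSE, N, N)
  constrainedFull[rows, ] <- !freeMask
  bHat <- rep(NA_real_, N)
  kapr <- sqrt(1 + (pi / 8) * rowQuadForm(W, Sigma0))
  bHat[rows] <- kapr * lgm - as.numeric(W %*% m)
  new("InferenceResult", What = Wfull, bHat = bHat, lambda = lambda,
      objTrace = trace, iterations = it, converged = converged,
      constrained = constrainedFull)
}

#' Choose the L1 weight to match a target sparsity
#'
#' Outer loop around \code{\link{fitMAP}}: bisection on \code{log(lambda)}
#' until the off-diagonal nonzero fraction of the fitted weights matches
#' \code{targetSparsity} (relative tolerance \code{tol}, default 2\%). The
#' nonzero fraction is non-increasing in \code{lambda}, which the bisection
#' relies on; fits are warm-started along the path.
#'
#' @inheritParams fitMAP
#' @param targetSparsity desired off-diagonal nonzero fraction in [0, 1]
#'   (e.g. the true connection probability).
#' @param tol relative matching tolerance.
#' @param maxSteps bisection step cap.
#' @param lambdaMin lower bracket edge.
#' @param ... passed to \code{\link{fitMAP}}.
#' @return A list with \code{lambda}, \code{result} (the matched
#'   \code{\link{InferenceResult}}), \code{achievedSparsity}, and
#'   \code{matched} (FALSE if the target was unreachable in the bracket).
#' @export
selectLambda <- function(stats, targetSparsity, nT = NULL, tol = 0.02,
                         maxSteps = 40L, lambdaMin = 1e-6, rows = NULL,
                         warn = TRUE, ...) {
  stopifnot(targetSparsity >= 0, targetSparsity <= 1)
  sm <- sanitizeMoments(stats, warn = warn)
  N <- length(sm$m)
  if (is.null(rows)) rows <- seq_len(N - stats@nStim)
  offdiag <- matrix(TRUE, length(rows), N)
  offdiag[cbind(seq_along(rows), rows)] <- FALSE
  sparsityOf <- function(res)
    mean(res@What[rows, , drop = FALSE][offdiag] != 0)

  S1off <- abs(sm$Sigma1[rows, , drop = FALSE][offdiag])
  lambdaMax <- max(S1off, lambdaMin * 10)
  fitAt <- function(lam, W0) fitMAP(stats, lambda = lam, nT = nT, rows = rows,
                                    W0 = W0, warn = FALSE, ...)

  if (targetSparsity == 0) {
    res <- fitAt(lambdaMax, NULL)
    return(list(lambda = lambdaMax, result = res,
                achievedSparsity = sparsityOf(res), matched = TRUE))
  }
  # Descend the lambda path from the sparse (stable) end with warm starts,
  # then refine by bisection between the bracketing grid points. Descending
  # is essential for the adjusted fixed-point iteration, which can diverge
  # when cold-started at near-zero regularization.
  nGrid <- min(20L, maxSteps)
  lams <- exp(seq(log(lambdaMax), log(lambdaMin), length.out = nGrid))
  best <- NULL
  W0 <- NULL
  lo <- lambdaMin; hi <- lambdaMax
  stepsUsed <- 0L
  for (lam in lams) {
    stepsUsed <- stepsUsed + 1L
    res <- fitAt(lam, W0)
    s <- sparsityOf(res)
    if (res@converged) W0 <- res@What
    if (is.null(best) ||
        abs(s - targetSparsity) < abs(best$achievedSparsity - targetSparsity))
      best <- list(lambda = lam, result = res, achievedSparsity = s)
    if (abs(s - targetSparsity) <= tol * targetSparsity)
      return(c(best, list(matched = TRUE)))
    if (s > targetSparsity) { lo <- lam; break }
    hi <- lam
  }
  if (lo == lambdaMin && best$achievedSparsity < targetSparsity)
    warning("target sparsity unreachable within the lambda bracket",
            call. = FALSE)
  W0 <- best$result@What
  for (step in seq_len(max(0L, maxSteps - stepsUsed))) {
    mid <- sqrt(lo * hi)
    res <- fitAt(mid, W0)
    s <- sparsityOf(res)
    if (res@converged) W0 <- res@What
    if (abs(s - targetSparsity) < abs(best$achievedSparsity - targetSparsity))
      best <- list(lambda = mid, result = res, achievedSparsity = s)
    if (abs(s - targetSparsity) <= tol * targetSparsity)
      return(c(best, list(matched = TRUE)))
    if (s > targetSparsity) lo <- mid else hi <- mid
  }
  warning("sparsity matching did not reach tolerance; returning closest fit",
          call. = FALSE)
  c(best, list(matched = FALSE))
}

#' Fold an external stimulus into the raster as observed pseudo-neurons
#'
#' Appends the \code{D x T} stimulus rows to the spike matrix and all-ones
#' rows to the mask, so the downstream moment and ELL code runs unchanged on
#' the augmented system. The fitted \code{(N+D) x (N+D)} weight matrix then
#' holds the connectivity estimate in its top-left \code{N x N} block and
#' the stimulus gain estimate in the top-right \code{N x D} block; the
#' stimulus rows themselves are excluded from fitting.
#'
#' @param raster a \code{\link{SpikeRaster}} (no prior augmentation).
#' @param mask an \code{\link{ObservationMask}} or \code{NULL}.
#' @param stimulus \code{D x T} stimulus matrix.
#' @return List with the augmented \code{raster} and \code{mask}.
#' @seealso \code{\link{splitAugmentedFit}}
#' @export
augmentStimulus <- function(raster, mask, stimulus) {
  stopifnot(is(raster, "SpikeRaster"), raster@nStim == 0L)
  stimulus <- as.matrix(stimulus)
  Tn <- ncol(raster@S)
  if (ncol(stimulus) != Tn) stop("stimulus and raster must have matching T")
  N <- nrow(raster@S); D <- nrow(stimulus)
  Snew <- rbind(raster@S, stimulus)
  r <- new("SpikeRaster", S = Snew, binWidth = raster@binWidth,
           s0 = c(raster@s0, numeric(D)), nStim = as.integer(D))
  O <- if (is.null(mask)) matrix(1L, N, Tn) else {
    stopifnot(all(dim(mask@O) == c(N, Tn)))
    mask@O
  }
  Onew <- rbind(O, matrix(1L, D, Tn))
  mnew <- new("ObservationMask", O = Onew,
              scheme = if (is.null(mask)) "custom" else mask@scheme,
              pObsTarget = mean(Onew))
  list(raster = r, mask = mnew)
}

#' Split an augmented fit into connectivity and stimulus-gain blocks
#'
#' @param result \code{\link{InferenceResult}} from a stimulus-augmented fit.
#' @param N number of neurons; \code{D} stimulus channels.
#' @param D number of stimulus channels.
#' @return List with \code{What} (\code{N x N}) and \code{Ghat} (\code{N x D}).
#' @export
splitAugmentedFit <- function(result, N, D) {
  stopifnot(nrow(result@What) == N + D)
  list(What = result@What[seq_len(N), seq_len(N), drop = FALSE],
       Ghat = result@What[seq_len(N), N + seq_len(D), drop = FALSE])
}
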
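#' @include AllClasses.R evalq.R
NULL

#' Build an experiment configuration
#'
#' A serializable description of one end-to-end run. Experiment durations
#' may be given in hours; they convert to bins at the fixed 10 ms bin width
#' (so 5.5 hours is 1,980,000 bins).
#'
#' @param N network size.
#' @param hours,nBins experiment length (give one; hours wins).
#' @param pObs observation fraction.
#' @param scheme observation scheme.
#' @param seed master seed.
#' @param binWidth bin width in seconds.
#' @param matchSparsity,lambda regularization control.
#' @param gradMode gradient mode.
#' @param network named list of \code{\link{networkConfig}} overrides.
#' @return List of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(N = 50L, hours = NULL, nBins = 1e5, pObs = 0.2,
                             scheme = "double_serial", seed = 1L,
                             binWidth = 0.01, matchSparsity = TRUE,
                             lambda = 0, gradMode = "adjusted",
                             network = list()) {
  if (!is.null(hours)) nBins <- as.integer(round(hours * 3600 / binWidth))
  cfg <- list(N = as.integer(N), nBins = as.integer(nBins), pObs = pObs,
              scheme = scheme, seed = as.integer(seed), binWidth = binWidth,
              matchSparsity = matchSparsity, lambda = lambda,
              gradMode = gradMode, network = network)
  if (cfg$nBins < 2) stop("experiment needs at least 2 bins")
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' Read / write experiment configurations as YAML
#'
#' \code{readExperimentConfig(path)} and \code{writeExperimentConfig(cfg,
#' path)} round-trip a configuration (\code{load(save(x)) == x}).
#'
#' @param path YAML file path.
#' @param cfg an \code{\link{experimentConfig}}.
#' @return The configuration (read) or the path, invisibly (write).
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experimentConfig, raw)
}

#' @rdname readExperimentConfig
#' @export
writeExperimentConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run one end-to-end experiment
#'
#' Simulate, observe, estimate moments, fit, and score; optionally write all
#' artifacts (network, raster, mask, moments, result, quality) plus a JSON
#' manifest with MD5 hashes to \code{outDir}. Reruns with an identical
#' configuration produce identical artifact hashes.
#'
#' @param cfg an \code{\link{experimentConfig}}.
#' @param outDir optional output directory.
#' @return The \code{\link{recoveryExperiment}} result list (plus
#'   \code{manifest} when written).
#' @export
runExperiment <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  netCfg <- do.call(networkConfig,
                    c(list(N = cfg$N, seed = childSeed(cfg$seed, 1)),
                      cfg$network))
  res <- recoveryExperiment(N = cfg$N, nBins = cfg$nBins, pObs = cfg$pObs,
                            scheme = cfg$scheme, seed = cfg$seed,
                            cfg = netCfg, matchSparsity = cfg$matchSparsity,
                            lambda = cfg$lambda, gradMode = cfg$gradMode)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(network = file.path(outDir, "network_w.tsv"),
               biases = file.path(outDir, "network_b.tsv"),
               what = file.path(outDir, "estimated_w.tsv"),
               quality = file.path(outDir, "quality.json"),
               config = file.path(outDir, "config.yaml"))
    writeMatrixTSV(weightMatrix(res$network), paths["network"])
    utils::write.table(data.frame(bias = biases(res$network)),
                       paths["biases"], sep = "\t", row.names = FALSE)
    writeMatrixTSV(estimatedWeights(res$fit), paths["what"])
    q <- res$quality
    jsonlite::write_json(list(S = q@S, Z = q@Z, C = q@C, R2 = q@R2,
                              signErrors = res$signErrors,
                              nNonzero = res$nNonzero,
                              lambda = res$lambda),
                         paths["quality"], auto_unbox = TRUE, digits = NA)
    writeExperimentConfig(cfg, paths["config"])
    manifest <- list(config = unclass(cfg),
                     files = as.list(tools::md5sum(unname(paths))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE)
    res$manifest <- manifest
  }
  res
}

#' Write / read a dense numeric matrix as TSV
#'
#' @param M matrix; \code{path} file path.
#' @param path file path.
#' @return The path (write) or the matrix (read).
#' @export
writeMatrixTSV <- function(M, path) {
  utils::write.table(M, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  M <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(M) <- NULL
  M
}

#' Write / read a raster or mask as sparse triplets
#'
#' Stores only the nonzero entries as (row, bin, value) triplets plus a JSON
#' sidecar with dimensions, bin width and initial state; suitable for the
#' very sparse matrices this package produces.
#'
#' @param raster a \code{\link{SpikeRaster}}.
#' @param path TSV path; the sidecar is \code{<path>.json}.
#' @return The path (write) or the reconstructed raster (read).
#' @export
writeRasterTSV <- function(raster, path) {
  S <- spikes(raster)
  idx <- which(S != 0, arr.ind = TRUE)
  utils::write.table(data.frame(neuron = idx[, 1], bin = idx[, 2],
                                value = S[idx]),
                     path, sep = "\t", row.names = FALSE)
  jsonlite::write_json(list(N = nrow(S), T = ncol(S),
                            binWidth = binWidth(raster),
                            s0 = initialState(raster),
                            nStim = raster@nStim),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRasterTSV
#' @export
readRasterTSV <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trip <- utils::read.table(path, sep = "\t", header = TRUE)
  S <- matrix(0L, meta$N, meta$T)
  if (nrow(trip)) S[cbind(trip$neuron, trip$bin)] <- as.integer(trip$value)
  new("SpikeRaster", S = S, binWidth = meta$binWidth,
      s0 = as.numeric(meta$s0), nStim = as.integer(meta$nStim))
}

#' Small deterministic fixtures with oracle values
#'
#' Builds the tiny instances used throughout the test suite, each paired
#' with an independently computed expected value: a null (disconnected)
#' Bernoulli network whose profile loglikelihood has the closed form
#' \code{-T sum_i h(m_i)}; a single self-coupled neuron whose stationary
#' rate follows from its two-state Markov chain; and a 2-neuron, 3-bin
#' raster with one missing entry whose Gibbs conditional is enumerable.
#'
#' @param seed RNG seed.
#' @return Named list of fixtures.
#' @export
makeFixtures <- function(seed = 1L) {
  # (1) disconnected Bernoulli network
  net0 <- networkParams(matrix(0, 4, 4), b = c(-2, -1, 0, 1))
  r0 <- simulateGLM(net0, nBins = 2000, seed = childSeed(seed, 1))
  st0 <- exactMoments(r0)
  bernoulliNull <- list(network = net0, raster = r0, stats = st0,
                        exactProfileELL = -ncol(spikes(r0)) *
                          sum(binaryEntropy(momentMean(st0))))

  # (2) self-coupled neuron: two-state Markov chain with
  # P(1|0) = sigma(b), P(1|1) = sigma(b + w); stationary rate p01/(p01+p10)
  w <- -3; bb <- 0.5
  p01 <- logistic(bb); p11 <- logistic(bb + w)
  stationary <- p01 / (p01 + (1 - p11))
  twoState <- list(network = networkParams(matrix(w, 1, 1), b = bb),
                   stationaryRate = stationary)

  # (3) enumerable Gibbs instance: exact conditional of the missing entry
  Wg <- matrix(c(-0.5, 1.2, -0.8, -0.5), 2, 2)
  bg <- c(-0.3, 0.2)
  Sg <- matrix(c(1L, 0L, 0L, 1L, 1L, 0L), 2, 3)
  Og <- matrix(1L, 2, 3); Og[1, 2] <- 0L
  logp <- function(s12) {
    S <- Sg; S[1, 2] <- s12
    fullLogLik(Wg, bg, spikeRaster(S, s0 = c(0, 0)))
  }
  l1 <- logp(1L); l0 <- logp(0L)
  gibbsEnum <- list(W = Wg, b = bg, S = Sg, O = Og,
                    conditionalP1 = 1 / (1 + exp(l0 - l1)))

  list(bernoulliNull = bernoulliNull, twoState = twoState,
       gibbsEnum = gibbsEnum)
}
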
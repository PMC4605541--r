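#!/usr/bin/env Rscript
# Optional long-running benchmark: a thousand-neuron network observed at
# 10-20% per bin over 5.5 hours of 10 ms bins. This is NOT part of the
# desk-scale acceptance run; expect on the order of an hour on one CPU and
# several GB of memory.
#
#   Rscript scripts/large-network.R --seed 1 --pobs 0.2 --out results/large.json

suppressPackageStartupMessages({
  library(optparse)
  library(shotgunconn)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--pobs", type = "double", default = 0.2),
  make_option("--n", type = "integer", default = 1000L),
  make_option("--out", type = "character", default = "results/large.json")
)))

nBins <- as.integer(5.5 * 3600 / 0.01)
res <- recoveryExperiment(N = opts$n, nBins = nBins, pObs = opts$pobs,
                          scheme = "double_serial", seed = opts$seed)
q <- res$quality
dir.create(dirname(opts$out), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(list(
  C = list(value = q@C, n = nBins),
  signErrors = list(value = res$signErrors, n = res$nNonzero),
  S = list(value = q@S, n = nBins),
  Z = list(value = q@Z, n = nBins)
), opts$out, auto_unbox = TRUE, digits = NA)
message(sprintf("N = %d, p_obs = %.2f: C = %.3f, %d sign errors / %d nonzero",
                opts$n, opts$pobs, q@C, res$signErrors, res$nNonzero))
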
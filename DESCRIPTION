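Package: shotgunconn
Title: Shotgun Inference of Neural Connectivity from Subsampled Spike Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the synaptic weight matrix of a recurrent spiking
    network from heavily subsampled activity recordings. Implements a
    scalable expected-loglikelihood (ELL) approximation to the generalized
    linear model (GLM) likelihood whose sufficient statistics are the first
    and second spike moments, which remain estimable when only a small,
    serially varying fraction of the network is observed in each time bin
    ("shotgun" sampling). Provides GLM and leaky integrate-and-fire
    simulators, observation-mask designs with identifiability diagnostics,
    missing-data moment estimation, L1-regularized MAP fitting by
    accelerated proximal gradient (FISTA) with sparsity-matched
    regularization, full-likelihood and Monte-Carlo EM baselines with Gibbs
    imputation of missing spikes, calcium-fluorescence forward simulation
    and spike deconvolution, and quantitative evaluation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'moments.R'
    'ell.R'
    'baselines.R'
    'observer.R'
    'netsim.R'
    'evalq.R'
    'fluor.R'
    'runner.R'
    'shotgunconn-package.R'
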
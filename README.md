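# shotgunconn

Synaptic connectivity inference for recurrent spiking networks from
heavily subsampled recordings.

Calcium imaging can cover large populations, but not all at once at the
temporal resolution connectivity estimation needs. Recording a fixed
subset instead runs into the **common input problem**: correlations driven
by unobserved neurons are mistaken for direct connections, a bias that no
amount of data removes. `shotgunconn` implements the *shotgun* answer —
serially observe many overlapping sub-populations so that every neuron
pair is eventually co-observed — together with an estimator that only
needs pairwise statistics and therefore tolerates such fragmentary
coverage. It is aimed at systems/statistical neuroscientists simulating
and benchmarking connectivity-inference designs.

## Model and estimator

Spiking is a discrete-time logistic GLM: with binary spikes `S[i,t]` and
input `U[,t] = W S[,t-1] + b + G X[,t]`,
`P(S[i,t] = 1) = 1 / (1 + exp(-U[i,t]))`. The target is the weight matrix
`W` (diagonal = post-spike self-effects), the biases `b`, and optionally a
stimulus gain `G`.

The estimator maximizes an **expected-loglikelihood (ELL)** approximation
of the profile likelihood,

    max_b log P(S | W, b)  ≈  T Σ_i [ Σ_j W_ij Σ¹_ij − h(m_i) √(1 + (π/8) W_i· Σ⁰ W_i·ᵀ) ],

which depends on the data only through the mean spike probabilities `m`
and the lag-0/lag-1 spike covariances `Σ⁰, Σ¹`. Under partial observation
these moments are estimated by re-normalized sums that ignore missing
entries — consistent whenever the observation mask eventually covers every
neuron pair. An L1 prior on the off-diagonal weights is handled by FISTA
(proximal gradient with Nesterov acceleration), with the regularization
weight matched to a target sparsity; each iteration costs `O(N³)` and
never touches the raster again. Full-likelihood MAP, Gibbs imputation of
missing spikes, Monte-Carlo EM, and a calcium-fluorescence
simulation/deconvolution front end are included as baselines and
end-to-end harnesses.

## Worked example

Simulate an hour of a 50-neuron cortical-like network, observe 20% of the
neurons per 10-ms bin with two interleaved serial scanners, and recover
the weights:

```r
library(shotgunconn)

net    <- generateNetwork(networkConfig(N = 50, seed = 1))
raster <- simulateGLM(net, nBins = 360000, seed = 2)   # 1 h of 10 ms bins
raster
#> SpikeRaster: 50 neurons x 360000 bins (10 ms bins)
#>   mean firing rate 3.08 Hz

mask <- makeMask("double_serial", N = 50, nBins = 360000, pObs = 0.2, seed = 3)
checkIdentifiability(mask)
#> Identifiability: all moments identifiable

stats <- estimateMoments(raster, mask)
Wtrue <- weightMatrix(net)
off   <- row(Wtrue) != col(Wtrue)
fit   <- selectLambda(stats, targetSparsity = mean(Wtrue[off] != 0))$result
fit
#> InferenceResult: 50 x 50 weights, lambda = 0.00049, 67 iterations (converged)
#>   off-diagonal nonzero fraction 0.173

qualityMetrics(Wtrue, estimatedWeights(fit))
#> QualityReport: S = 0.365, Z = 0.858, C = 0.809, R2 = 0.385
```

Even though only ten neurons are visible in any bin, the inferred weights
correlate with the truth at `C = 0.81`; the sparsity-matched L1 penalty
sets 86% of the truly absent connections exactly to zero (`Z`), at the
price of shrinking many weak true weights to zero as well (low `S` — the
sign score counts those as misses). Longer experiments and higher
observation fractions push `C` toward 1; `scalingScan()` maps the
trade-off, which collapses on `T ∝ N / p_obs²`.

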
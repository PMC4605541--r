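---
title: "Shotgun connectivity inference: model, method, and design choices"
author: "shotgunconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shotgun connectivity inference: model, method, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunconn)
```

## The problem

Estimating synaptic connectivity from activity recordings is obstructed by
the *common input problem*: when only part of a network is recorded,
correlations induced by shared unobserved inputs masquerade as direct
connections, and this bias does not vanish with more data. The package
implements a *shotgun* strategy: instead of watching one fixed subset of
neurons at high rate, the recording serially visits many overlapping
subsets, so that over the whole experiment every neuron pair is eventually
co-observed. Because the estimator below only needs pairwise spike
statistics, such fragmentary coverage is enough to recover the full weight
matrix.

## Model

Spiking follows a discrete-time logistic GLM. With binary spikes
$S_{i,t} \in \{0,1\}$ in bins of width $\Delta$ (10 ms by default),

$$
U_{\cdot,t} = W S_{\cdot,t-1} + b + G X_{\cdot,t}, \qquad
P(S_{i,t} = 1 \mid U_{i,t}) = \sigma(U_{i,t}) = \frac{1}{1+e^{-U_{i,t}}}.
$$

$W$ is the $N \times N$ connectivity (diagonal entries are post-spike
self-effects such as refractoriness), $b$ the biases, and $G$ an optional
gain on external stimuli $X$. Observations are flagged by a binary mask
$O_{i,t}$; only masked entries of $S$ are available to the estimator.

## The expected-loglikelihood estimator

The exact loglikelihood sums $S_{i,t}U_{i,t} - \log(1+e^{U_{i,t}})$ over
all bins and cannot be evaluated with missing spikes. Two approximations
remove the raster from the problem. First, time averages of the
loglikelihood are replaced by expectations under the empirical input
distribution; second, the input $U_{i,t}$ — a sum over many presynaptic
terms — is treated as Gaussian, using the closed form

$$
\int \log(1+e^x)\,\mathcal N(x \mid \mu, \sigma^2)\,dx \approx
\kappa \, \log(1+e^{\mu/\kappa}), \qquad \kappa = \sqrt{1 + \pi\sigma^2/8}
$$

(`gaussianSigmoidIntegral()`). Profiling out the biases analytically
(`recoverBias()`, $b_i = \kappa_i\,\mathrm{logit}(m_i) - \sum_k W_{ik}m_k$)
yields the profile objective implemented by `profileELL()`:

$$
\max_b \log P(S \mid W, b) \approx
T \sum_i \Big[ \textstyle\sum_j W_{ij}\,\Sigma^{(1)}_{ij}
  - h(m_i)\,\sqrt{1 + \tfrac{\pi}{8} W_{i\cdot}\Sigma^{(0)}W_{i\cdot}^\top}
\Big],
$$

with $m$ the mean spike probabilities, $\Sigma^{(0)}, \Sigma^{(1)}$ the
lag-0/lag-1 spike covariances, and $h$ the Bernoulli entropy. The data
enter only through $(m, \Sigma^{(0)}, \Sigma^{(1)})$ — approximate
sufficient statistics. Under partial observation these are estimated by
re-normalized sums that simply ignore missing entries
(`estimateMoments()`):
$\tilde m_i = \langle O S\rangle / \langle O \rangle$ and likewise for the
covariances with joint observation counts. The estimates are consistent
whenever every neuron (and neuron pair, at lags 0 and 1) is observed a
positive fraction of the time — exactly what `checkIdentifiability()`
diagnoses for a mask.

Fitting maximizes the profile objective plus an L1 log-prior on the
off-diagonal weights by FISTA (`fitMAP()`): proximal gradient steps with
Nesterov acceleration, soft-thresholding, per-row constant step sizes from
a power-iteration curvature bound, and a monotone restart. The objective
decomposes over rows of $W$, each iteration costs $O(N^3)$, and the raster
is never revisited after the single moment pass. `selectLambda()` wraps the
fit in an outer loop that matches the fitted off-diagonal nonzero fraction
to a target sparsity (such as the true connection probability), descending
the regularization path from the sparse end with warm starts and refining
by bisection.

### The adjusted gradient

The closed-form integral is accurate near the bulk of the logistic but
degrades for strongly negative means — precisely the regime of
low-firing-rate cortical neurons. Differentiating the *exact*
loglikelihood first and applying the expectation approximation afterwards
gives a more accurate stationary condition. For a binary presynaptic
column the gradient entry becomes

$$
\Sigma^{(1)}_{ij} + m_i m_j - m_j\,
\sigma\!\left(\frac{\mu_i + c_{ij}/m_j}{\kappa_{ij}}\right),
\qquad c = W\Sigma^{(0)},
$$

where conditioning on $S_{j,t-1}=1$ fixes the direct $W_{ij}$ contribution
to the input, so the Gaussian integral uses the *conditional* variance
$\sigma_i^2 + W_{ij}^2\Sigma^{(0)}_{jj} - 2W_{ij}c_{ij}$ inside
$\kappa_{ij}$. For real-valued stimulus columns the binary conditioning
does not apply; there Stein's lemma gives
$\Sigma^{(1)}_{ij} - c_{ij}\,m_i(1-m_i)/\kappa_i$. We validated this field
against a Monte-Carlo estimate of the expected exact gradient (one million
simulated bins, batch-means error bars): the unconditional-variance form
carries a visible linearization bias on refractory diagonals, while the
conditional form agrees within Monte-Carlo noise. Having passed that
validation, `gradMode = "adjusted"` is the default for `fitMAP()`; the
plain objective gradient (`"objective"`) remains available and is the one
checked against finite differences. In practice the adjusted fit removes
essentially all of the global weight shrinkage the raw objective induces
at 3 Hz rates (regression slope of estimate on truth ≈ 1.0 versus ≈ 0.27
at full observation, $N = 30$).

Two safeguards matter under noisy moments. The adjusted field is a fixed
point, not a gradient: its accelerated proximal iteration uses an
iterate-change stopping rule, a gradient-scheme adaptive restart, a damped
re-start on divergence, and a generous box constraint
(`weightBound = 10`). The box handles a real small-sample pathology: when
an empirical lag-1 self-moment falls below the smallest value the field can
reproduce (e.g. zero observed consecutive self-spike pairs under strong
refractoriness), the maximizing self-weight is $-\infty$ and the entry pins
harmlessly at the bound instead of running away. Covariance entries whose
joint observation count is zero are kept as flags (`NA`), entered into the
objective as zeros, and their weights are constrained to zero — silent
fabrication would hide exactly the identifiability failures the mask
diagnostics are for. A non-positive-definite plug-in $\Sigma^{(0)}$ is
handled by clipping row quadratic forms at zero (eigenvalue projection is
available via `psd = "eigen"`).

## Observation schemes

`makeMask()` implements five schemes: a fixed subset (the conventional
design; never identifies the unobserved rows), a serial scanner (never
co-observes pairs further apart than its block), fully random bins
(identifies everything but is experimentally unrealistic), random blocks
held over a dwell time, and *double serial scanning* — two serial scanners
with different dwell times. For the double scanner we give the second
scanner $N+1$ phases (it pauses one extra dwell per sweep) so the two cycle
lengths can be made coprime; by the Chinese remainder theorem the joint
phase pattern then sweeps every position pair within one super-period, and
every neuron pair is eventually co-observed. The default dwell times (13
and 17 bins) give a super-period of about 5.6e5 bins at $N = 50$, several
times shorter than the benchmark experiment.

## The synthetic cortical generator

`generateNetwork()` draws the ground truth the simulations use: Dale's law
with 20% inhibitory neurons; off-diagonal connections present independently
with probability `pConn = 0.163`; excitatory magnitudes log-normal with
median 0.178 so most are weak and a few strong; inhibitory magnitudes three
times larger; a fixed self-weight of −3 per neuron modelling
refractoriness; and Gaussian biases per class tuned so a 50-neuron network
fires near 3 Hz overall with inhibitory neurons roughly twice as fast as
excitatory ones. These values reconstruct a mouse-visual-cortex-like
operating point: the connection count (~448 nonzero weights at $N=50$
including the diagonal), the excitatory weight median, and the 3 Hz rate
are the anchors, and the remaining scales were calibrated once against the
benchmark correlation target and then frozen. The generator emulates
stationary spontaneous activity only — no dale-breaking synapses, no
distance dependence, no adaptation or oscillatory structure, no
multi-spike bins — so passing tests certify the estimator under model
match (plus the LIF mismatch below), not performance on arbitrary real
recordings.

`simulateGLM()` runs the model exactly (all-zero initial state, 1000
burn-in bins discarded). `simulateLIF()` provides a deliberately
mismatched neuron: $V_{i,t} = (\gamma V_{i,t-1} + (1-\gamma)U_{i,t} +
\varepsilon_{i,t})\,\mathcal I[S_{i,t}=0]$ with a spike when $V$ crosses
0.5 and a reset in the spiking bin (one bin of absolute refractoriness).
The membrane decay uses $\gamma = e^{-\Delta/\tau_m}$ with $\tau_m = 20$
ms (a membrane timescale quoted as an inverse rate is dimensionally
inconsistent with a per-bin decay factor, so the exponential-decay reading
is adopted); both are exposed in `lifConfig()`.
Simulators draw from R's RNG under a single integer seed (one stream per
simulation; bitwise reproducible), rather than per-neuron counter
substreams — the C++ inner loop is the only consumer, so substreams would
buy nothing.

## Baselines

`fitMAPFull()` is the conventional estimator: FISTA on the exact
(penalized) loglikelihood, jointly in $(W, b)$, $O(N^2 T)$ per iteration.
Its per-coordinate steps come from a Gershgorin diagonal majorizer of the
covariate second-moment matrix — with rare binary covariates a single
scalar step is hopelessly conservative. It requires full observation; at
low firing rates and tiny $N$ the likelihood can have near-flat ridges, so
oracle comparisons against `glm()` are run at moderate rates.
`gibbsImpute()` resamples missing spikes from their full conditionals
(systematic $(t, i)$ scan, observed entries frozen); `emStep()` alternates
imputation (30 burn-in sweeps plus one retained sample), exact moments on
the completed raster, and an ELL refit at the same regularization. The
Gibbs inner loop replaces all exponentials with per-edge interpolation
tables of softplus differences (grid step ~0.01, absolute error below
1e-5, far below Monte-Carlo noise; checked against exact enumeration on
tiny instances).

## Fluorescence

`simulateFluorescence()` renders an AR(1) calcium indicator
($c_t = e^{-\Delta/\tau}c_{t-1} + s_t$, GCaMP6f-like $\tau = 0.4$ s,
rise time folded into the bin) with additive Gaussian noise of standard
deviation `snr * amplitude` — following imaging convention here, larger
`snr` means a *noisier* trace (0.2 low noise, 0.4 high).
`inferSpikes()` inverts it by nonnegative AR(1) deconvolution (pool
adjacent violators), thresholding innovations at half the unit response;
deterministic, exact on noiseless isolated transients.
`fluorescencePipeline()` chains simulation, imaging, deconvolution,
masking, moments, and fitting next to a true-spike control.

## Numerical choices and problem sizes

Tolerances: FISTA stops at relative objective change $10^{-9}$ (iterate
change $\sim 3\times10^{-5}$ for the adjusted field) or 5e4 iterations;
sparsity matching uses a ±2% relative tolerance with at most 40 fits;
$\lambda$ is bracketed by $[10^{-6}, \max|\tilde\Sigma^{(1)}_{ij}|]$. Ties
and degenerate inputs: silent neurons are an error wherever a logit is
required; an all-zero truth makes correlation scores `NA` rather than 0.

The test suite runs scaled-down versions of the large experiments: the
benchmark protocol ($N=50$, 5.5 h of 10 ms bins, $p_{\rm obs} = 0.04$,
double serial scanning, sparsity-matched $\lambda$) over 5 seeds; the
common-input demonstration at $T = 10^6$ rather than $5\times10^8$,
testing the *persistence* contrast (fixed-subset bias survives longer
experiments, shotgun bias shrinks) rather than figure-exact values; EM
comparisons at $N=50$, $T=5\times10^5$, 10 seeds; and the single-neuron
experiment with hundreds rather than $10^4$ inputs. A thousand-neuron run
is a straightforward (if hours-long) call to the same functions:
`recoveryExperiment(N = 1000, nBins = 2e6, pObs = 0.2)`.

## Known limitations

Only one history lag is modelled (no extended post-spike filters); bins
are strictly binary; the ELL surface's quality degrades quadratically with
overall weight scale at very small $N$ (the Gaussian-input step needs many
presynaptic contributions), which is why tiny-network oracle checks use
moderate weights; the closed-form integral is weakest for strongly
negative means, mitigated but not removed by the adjusted gradient; and
refractory self-weights are only weakly identified in short experiments
(few consecutive self-spike pairs), where they may pin at the box
constraint. None of these affect the operating regime the method targets
— sparse, large, low-rate networks observed for hours.
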
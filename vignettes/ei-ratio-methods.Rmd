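---
title: "Methods: volume-constrained sparse coding and the E:I ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volume-constrained sparse coding and the E:I ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eisparse)
```

## The scientific question

Across mammalian species the total number of cortical neurons spans several
orders of magnitude, yet the ratio of excitatory to inhibitory neurons (the
E:I ratio) stays within a narrow band of roughly 3:1 to 9:1. `eisparse`
implements a normative account of that regularity: if a sensory circuit
performs sparse coding under a fixed *volume* budget — modeled as a fixed
total neuron count `N = N_E + N_I` — then there is an interior E:I ratio at
which stimulus reconstruction, population sparsity and metabolic cost are
simultaneously optimized, and that optimum shifts upward with the sparsity
level of the code.

## The model

### Sparse coding objective

A stimulus patch `I` (vectorized, dimension `d = patch_side^2`) is encoded
by the activities `a` of `N_E` excitatory cells with receptive fields
`phi_i` (columns of `Phi`, unit norm), chosen to minimize

    E(a) = 1/2 ||I - Phi a||^2 + lambda ||a||_1 .

We use the convention with the factor 1/2 on the quadratic term throughout:
it is the convention under which the soft-threshold fixed point of the
circuit dynamics below is exactly the minimizer (the threshold equals
`lambda`), and it matches the scalar case `Phi = [1], I = 2, lambda = 0.5
-> a = 1.5`. Codes are signed; wherever activities are interpreted as
firing rates (sparsity, energy, interneuron statistics) their magnitudes
are used, since rates cannot be negative.

### Circuit implementation (LCA)

The locally competitive algorithm integrates

    tau du/dt = Phi' I - u - W a,   a = T_lambda(u)

with `T_lambda` the soft threshold. With the ideal recurrent matrix
`W = G - I`, `G = Phi' Phi`, the fixed points minimize `E(a)`. The
interactions in `G` must be carried by physical connections: its positive
entries require inhibition, and the model implements them disynaptically
through `N_I` interneurons via the rank-`N_I` truncated eigendecomposition
(equivalently SVD, `G` being symmetric PSD) `G ~ U S V'`. Columns of `V`
are E-to-I input weights, `S` holds non-negative dendritic gains, columns
of `U` are I-to-E output weights, and interneuron activities are read out
as `b = V' a`. Eckart–Young makes `U S V'` the Frobenius-closest rank-`N_I`
approximation, so `N_I` — the volume spent on interneurons — directly
controls how faithfully the required competition can be implemented.

### Why the self term stays a leak

A literal `W_approx = U S V' - I` is ill-posed below full rank: the
effective quadratic form `U S V'` is rank-deficient while the stimulus
drive `Phi' I` generally has components outside its range, so the
integration drifts without bound (we verified this: the state grows
linearly with a constant residual). The package therefore keeps the
diagonal out of the truncation:

    W_approx = U S V' - diag(U S V') ,

i.e. the interneurons carry the couplings *between distinct* excitatory
cells, while each cell's self term remains an ordinary leak. The effective
interaction `U S V' + (I - diag(U S V'))` is then positive definite (the
diagonal of `G` is 1 for unit-norm features, and the truncated diagonal
never exceeds it), the dynamics converge at every rank, and at
`N_I = N_E` the matrix equals `G - I` to machine precision, recovering the
ideal circuit exactly. This is a deliberate design choice of the package,
made where the source model is silent on well-posedness below full rank.

A `rectify` option zeroes negative entries of `U` and `V` for structural
analyses that read them as synaptic weight sets; the dynamics default to
the raw factors, which carry the optimal approximation.

### Performance measures

For each evaluation patch, with rates `|a|` and `|b|`:

* reconstruction error `||I - Phi a|| / ||I||`;
* Treves–Rolls population sparsity
  `TR = [1 - (sum a_i / N_E)^2 / (sum a_i^2 / N_E)] / (1 - 1/N_E)`,
  computed over excitatory cells only (interneurons are modulatory and not
  part of the represented code); density is `1 - TR`; an all-silent
  response leaves TR undefined and is excluded from averages;
* metabolic energy
  `(3.42 N + 7.1 sum|a_i| + 7.1 sum|b_j|) x 1e8` ATP/s — a resting cost
  per neuron plus a per-spike cost times rate, treating E and I spikes as
  equally expensive;
* pooled I-to-E weight sample: the entries of `U %*% diag(S)` (gain folded
  into the output synapses), whose kurtosis (Pearson convention,
  normal = 3) quantifies how targeted versus global inhibition is;
* total inhibitory influence: the mean over stimuli of the summed positive
  entries of the drive `U S b` delivered to E cells. No formula for this
  quantity is standard; this definition (current actually delivered with
  inhibitory sign, combining rates and synaptic strengths) is the
  package's documented choice.

For cross-lambda comparison each measure is normalized per lambda so its
grid minimum maps to 0 and its value at the 1:1 anchor to 1; when the
minimum *is* the 1:1 value the series is returned unnormalized with a
degeneracy flag rather than silently rescaled.

## The sweep

`run_sweep()` evaluates a grid of `(lambda, N_E)` cells under fixed `N`. A
dictionary is trained *per cell* (the receptive fields an E population can
afford depend on its size and on lambda), the circuit is built with
`N_I = N - N_E`, a shared evaluation patch set is encoded, and all
measures are aggregated. Standard errors come from a bootstrap whose
resampling unit is the source image (then its patches), honoring the
strong within-image correlation of patches. Per-measure optima are located
by grid argmin with local quadratic interpolation (the study reports a
fractional optimum, so some interpolation rule is required; a parabola
through the argmin and its neighbors is the minimal one), with uncertainty
from re-finding the optimum on bootstrap-resampled series and a boundary
flag when the argmin sits at the grid edge.

### Dictionary training

Alternating minimization: FISTA infers codes for a minibatch, each atom
takes a relaxed exact minimization step along its residual direction
(a per-atom normalized residual step, scale-free in the data), and columns
are renormalized to unit norm after every update; collapsed atoms are
reseeded. Held-out energy is checkpointed and a rising trend triggers
step-size back-off. Batch size 100, 100–250 updates and ~2000 training
patches suffice at the problem sizes below; all settings are exposed.

### Problem sizes

The full protocol (16x16 patches, `N = 1200`, the 10-image 512x512
pre-whitened natural database) is expressible via `full_scale_config()`;
its dictionary training is a many-hour computation. The package's standard
desk-scale replication (`desk_scale_config()`) — used by the test suite
and the acceptance script — is an exact quarter-scale preservation of the
geometry: 8x8 patches (`d = 64`), `N = 300` (so `N/d ~ 4.7`, as at full
scale), an 8-point ratio grid from 1:1 to 14:1,
`lambda in {0.05, 0.15, 0.3}`, ten synthetic 1/f images, 1500 training
patches and 80 update steps per cell, 40 evaluation patches, 150
bootstrap replicates — a three-lambda sweep runs in minutes on one CPU.
At this scale the 1:1 cell is ~2.3x
overcomplete, matching the full-scale study; with a much smaller budget
(e.g. `N = 120`, making the 1:1 cell undercomplete) the error optimum
collapses to the 1:1 boundary — the geometry, not just the size, carries
the phenomenon. Inhibition-trend analyses that need several seeds use a
further-reduced 6x6 / `N = 170` configuration with the same `N/d`
(`trend_scale_config()`: 5 ratio points, 800 training patches, 40 updates
and 24 evaluation patches per cell).

## Synthetic stimuli

Natural-image surrogates are Gaussian random fields with radially averaged
amplitude spectra proportional to `f^-1` — the standard minimal surrogate
for natural second-order statistics, which is what drives the overlap
structure of learned dictionaries and hence the inhibition budget. They do
not contain edges, occlusions or higher-order dependencies, so passing
desk-scale tests shows the mechanism (capacity-versus-computation
trade-off under a volume constraint), not a quantitative prediction for
real images; real images are supported through `load_images()` with an
optional ramp whitening filter (`f exp(-(f/f0)^4)`), defaulted ON for
loaded raw images and OFF for the surrogates (which need no deconvolution
of a camera/display chain and are used unwhitened to keep their spectra
controlled).

Planted-dictionary patches (`generate_planted_patches()`) give a known
ground truth for recovery tests: random unit-norm atoms, Bernoulli–Laplace
coefficients, Gaussian pixel noise, stored so `patches = coefficients %*%
t(dictionary) + noise` holds exactly.

Hierarchical spike data (`generate_hier_spikes()`) emulate multi-level
electrophysiology: Poisson counts per neuron and bin with log-normal
multiplicative rate effects at subject and session level (sd 0.2 by
default — enough dependence to make pseudoreplication visible without
swamping the signal). Population sparsity of the synthetic data is
steered by skewing the per-neuron base rates.

## Population sparsity in spike data and the hierarchical bootstrap

`trial_sparsity()` applies the TR statistic per time bin across neurons
(100 ms bins are conventional for natural-stimulus comparisons) and
averages over bins with at least one spike; TR is undefined in silent
bins. Model activities and spike counts are not directly comparable on
the TR scale (the statistic is sensitive to binning and dynamic range), so
cross-group comparisons are always within-data-type.

`hierarchical_bootstrap()` resamples subjects, then sessions within each
resampled subject, then trials within each session, with replacement,
averaging trial TRs into one group mean per replicate. Neurons are *not*
resampled: TR is a statistic of the recorded population, and resampling
neurons would change the estimand; a naive trial-pooled variant is
provided (`method = "pooled"`) as the anticonservative comparator. The
directed `p` for "A sparser than B" is the fraction of replicates with
`meanTR_A <= meanTR_B`. Family-wise control across several directed
hypotheses uses Bonferroni (`compare_groups()`), matching conservative
practice for small hypothesis families.

## Numerical choices

* FISTA step `1/L` with `L` the largest eigenvalue of `G`; convergence on
  max absolute iterate change (default 1e-8, 1e-12 in oracle tests).
* LCA forward Euler with `dt/tau = 0.1`, tolerance 1e-6 on `max|du|` per
  step, cap 2000 steps (2500 and 2e-5 in the sweep, where thousands of
  encodings run); divergence guard at `|u| > 1e8` aborts with a
  diagnostic; non-convergence is flagged in the result, not raised.
* Zero initialization `u(0) = 0`, the standard LCA start.
* Eigenvector sign ambiguity in the factorization is fixed by requiring
  each interneuron's input weight sum to be non-negative.
* Ties and degeneracies: all-zero rate vectors yield `NA` sparsity
  (excluded from means); zero singular values are kept as zero gains;
  optimum-at-anchor normalization is flagged, never guessed.
* Quadratic interpolation of optima is clamped to the bracketing grid
  interval, and negative-curvature fits fall back to the grid argmin.

## Known limitations

* Below full rank the truncated circuit solves a perturbed objective; no
  claim is made that reconstruction error is monotone in `N_I` at fixed
  dictionary — weakened competition can densify codes and *reduce*
  reconstruction error while sparsity collapses. The guaranteed ordering
  (tested) is on the exact objective: truncated codes never beat the
  full-rank code.
* Rate-based dynamics only; no spiking LCA variants.
* The volume constraint counts somata only — no cell-type volume
  differences, axonal/dendritic volume, or glial energy costs.
* Interneurons are generic: no genetic subtypes, no Dale's-law-constrained
  learning of the factorization.
* No loaders for specific public electrophysiology archives; spike data
  enter through the flat CSV/structured formats.
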
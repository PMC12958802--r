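---
title: "Comparing kernel and network models for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing kernel and network models for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelpred)
```

## Scope and model

`kernelpred` supports head-to-head comparisons of reproducing kernel
Hilbert space (RKHS) regression and feed-forward networks across prediction
problems that differ in their predictand: breeding values (additive genomic
data only), hybrid values (adding dominance), total genetic values (adding
non-linear genomic kernels), phenotypes (adding environmental data and
interactions), and site means (environmental data only). The taxonomy is
enforced at evaluation time: a model whose input modalities exceed the
problem's set is rejected rather than silently scored, because a comparison
across predictands confounds model skill with information content.

The RKHS side fits

$$y = 1\mu + \sum_k u_k + \varepsilon, \qquad
u_k \sim N(0, K_k \sigma_k^2), \quad \varepsilon \sim N(0, I\sigma_\varepsilon^2)$$

by Gibbs sampling. Writing $K_k = U_k \Lambda_k U_k'$ and $u_k = U_k b_k$
with prior $b_k \sim N(0, \Lambda_k \sigma_k^2)$ turns every coefficient
full conditional into an independent Gaussian, because the eigenvectors are
orthonormal over the full record set. Records to be predicted enter the
kernels but not the likelihood: their responses are treated as missing and
imputed from the current conditional distribution in each sweep, which is
an exact data-augmentation scheme — the marginal posterior of all
parameters is the one conditioned on the observed (training) records only,
while every conditional stays diagonal. Posterior predictions are the
posterior means of $\mu + \sum_k u_k$ at the requested records.

### Kernels

* **Linear** — $K = XX'/(\mathrm{tr}(XX')/n)$. The trace normalization puts
  kernels of different predictor sets on a common scale (trace $= n$), so
  their variance components are comparable within the multi-kernel model.
* **Gaussian** — $k_{ii'} = \exp(-h\, d^2_{ii'}/q)$ with $q$ the median of
  the *off-diagonal* squared Euclidean distances. Including the zero
  diagonal would bias $q$ downward, so it is excluded. The bandwidth $h$
  is unitless thanks to the $q$ scaling.
* **Arc-cosine** — depth-$l$ recursion of the ReLU arc-cosine kernel,
  the covariance function of an infinite-width single-hidden-layer ReLU
  network. Floating-point overshoot of the $\arccos$ argument on (near-)
  identical vectors is clipped to $[-1, 1]$ within $10^{-12}$; larger
  violations raise an error rather than being silently truncated. The
  recursion yields a non-unit diagonal; the kernel is used as produced
  (no cosine normalization) so that its scale information reaches the
  variance component, and the depth hyperparameter is stored with the
  kernel.

Per-variable weather kernels are combined into one composite: linear
constituents are summed and trace-normalized (each covariate implicitly
equal-weighted); Gaussian and arc-cosine constituents are averaged with
weights proportional to the inverse of each variable's optimized
hyperparameter, normalized to sum to one. Inverse-hyperparameter weighting
upweights variables whose optimum indicates strong global similarity; the
normalization keeps the composite's diagonal at one for Gaussian
constituents.

Interaction kernels use the Hadamard product of level-expanded kernels,
$(Z_a K_a Z_a') \circ (Z_b K_b Z_b')$, which is positive semi-definite by
the Schur product theorem; substituting an identity kernel for one factor
gives the "unstructured" version of that factor (e.g. additive effects
independent across environments). Expanded kernels are eigendecomposed
exactly with truncation at eigenvalues below $10^{-10}$ or 7,500
components, whichever binds first; at the problem sizes this package
targets the tolerance rule always binds, and the basis records the captured
fraction of positive eigenmass.

### Hyperparameter optimization

Bandwidths and depths maximize the marginal likelihood of the training
responses under $y = g + \varepsilon$, evaluated in the kernel eigenbasis
where the rotated components are independent; directions dropped by
truncation contribute pure-noise terms, so the likelihood is exact for any
retained rank. At each candidate hyperparameter the variance ratio
$\sigma_g^2/\sigma_\varepsilon^2$ is profiled by a one-dimensional search
on the log scale over $[e^{-10}, e^{10}]$, with $\sigma_\varepsilon^2$
itself profiled analytically. The bandwidth search is a bounded scalar
optimization over $[0.05, 6.0]$ by default — optimized bandwidths in this
literature cluster at exactly these box constraints, so they are exposed as
arguments — and the returned fit carries a boundary flag, which is also
what a flat, pure-noise profile produces. Depth search is an exhaustive
integer grid ($l \le 50$ by default; reported optima in comparable analyses
stay below 35). Responses are centered before optimization; all model
fitting operates on train-standardized responses, and the cited procedures
being otherwise underdetermined, the standard spectral Gaussian-process
marginal likelihood with a profiled ratio is used as the operational
definition throughout.

### Priors and chain settings

Every variance carries a scaled-inverse-chi-square prior with 5 degrees of
freedom; the scale is set so the prior mode equals
$\mathrm{var}(y_{\text{train}})/(\text{number of kernels} + 1)$, a weakly
informative equal-split of the phenotypic variance. $\mu$ has a flat prior.
Default chain settings are 15,000 iterations, 5,000 burn-in, thinning 5
(2,000 retained draws); the package's own tests and scripts use shorter
chains (about 1,200–4,000 iterations) at their problem sizes, where
mixing is fast because all conditionals are diagonal. Each kernel draws
from an RNG stream keyed by its *name*, so the randomness attributed to a
kernel does not depend on its position in the kernel list; exact
bit-invariance under reordering is impossible for any Gibbs sampler (each
full conditional depends on the current values of the other blocks), and
reordering is instead checked to leave posterior means unchanged within
Monte Carlo error.

## The network arm

The network engine implements the three module shapes used in this setting:
dense stacks (affine, activation, inverted dropout) for genomic, soil, and
fusion inputs; and a 1-D convolutional stack over the weather window axis
(blocks of valid-mode convolutions followed by max or average pooling)
flattened into the single linear output unit. Training is mini-batch Adam.
The squared-error loss is minimized — its gradient equals the RMSE gradient
up to a positive factor, so the minimizers coincide — and all reported
losses are RMSE. Weight initialization is He-scaled for ReLU and
Glorot-scaled otherwise; replicate seeds control initialization, batch
shuffling, and dropout masks, giving bit-reproducible runs on a fixed
platform and statistically reproducible runs across platforms.

The tuning protocol mirrors the replicated-validation design used for the
comparison: training/validation pairs are formed by holding out whole
site-years from the training set (16 of them per pair at full scale, 10
pairs); each of up to 40 random configurations is trained on one randomly
chosen pair with early stopping (patience 7, up to 500 epochs) and scored
by its best-epoch validation RMSE (the criterion for "best performing" in
the initial ranking being otherwise unspecified, best-epoch loss is used
and recorded). The four best configurations are retrained on every pair
for the full epoch budget; per epoch, the mean plus standard deviation of
the validation loss across pairs is averaged within ten equal-width epoch
bins, and the configuration winning the most bins is selected. A tie in
bins won — possible with discrete trajectories — is broken by fewest
parameters, then lowest overall mean validation loss. The epoch count is
the earliest minimizer of the trailing 20-epoch rolling mean of the summed
validation loss. Final models are trained in 10 independently seeded
replicates; fusion training sets concatenate the final-layer features of
one randomly chosen replicate per modality, so single-model sampling
variability propagates into the fusion stage. Random search (with the
proposal mechanism pluggable) replaces Bayesian optimization in the
candidate-generation step: the selection and evaluation protocol, not the
proposal distribution, is the analysis-relevant computation.

## The synthetic generator

The generator produces data with the statistical structure the analysis
assumes, not a portrait of any real population:

* **Panel** — independent biallelic loci, reference frequency uniform over
  the configured MAF range (default 0.03–0.5, matching the usual MAF
  filter), fully homozygous inbreds, with rejection of loci whose realized
  MAF falls below the lower bound. Linkage disequilibrium is absent by
  default; real-panel LD is empirical and not reproducible from published
  summaries.
* **Design** — each line crossed to a cyclic block of testers; hybrid
  genotypes are exact parental averages, $\tfrac12 MX$.
* **Environments** — site-level soil vectors (shared exactly across years
  of a site) and per-site-year daily weather: site and year level shifts
  plus a random-phase seasonal wave and day-level noise over days −75..204
  (280 days, giving 93 full 3-day windows plus a 1-day trailing window —
  94 in all; the published 94-window configuration over 280 days forces
  one partial window, taken here at the trailing end).
* **Phenotypes** — $y = \mu + a + d + i + g{\times}e + e + \varepsilon$
  with additive and dominance terms from the corresponding codings,
  epistasis as additive×additive products over random locus pairs (the
  simulation's operational definition — kernels only ever *fit* epistasis,
  they do not define a generating model), a rank-1 genotype-by-environment
  term (per-hybrid additive score times a per-environment index — the
  simplest structure an interaction kernel can identify), an environment
  main effect built from soil and season-mean weather, and iid residuals.
  Each component is rescaled so its realized variance equals the requested
  fraction exactly; the standardized scale is then affine-mapped to a
  plausible grain-yield range (150 ± 25 bu/ac). Default fractions
  (0.30/0.05/0.10/0.10/0.25/0.20) reflect a heritable yield trait in a
  multi-environment trial.
* **Splits** — whole site-years are held out for testing (default 16 at
  full scale) and any site-year is capped at 265 records by random
  down-sampling, reproducing the "tested genotypes in untested
  environments" structure. Allele frequencies used for coding are computed
  from the panel being coded (the reference population for coding being
  otherwise unspecified, training-side frequencies are the natural choice
  and are what the split provides).

What passing tests on these data do **not** show: robustness to LD
structure, allele-frequency spectra shaped by selection, pedigree depth,
non-random missingness, or heterosis mechanisms — none of which the
generator emulates.

## Study conditions used by the tests and script

Problem sizes were chosen so each check is well-identified at desk scale:

* Kernel-class comparison under epistasis: 80 loci, 40 interacting pairs,
  300 hybrids (3 testers × 100 lines), variance fractions 0.2 additive /
  0.6 epistatic / 0.2 residual, 20% of records held out. Epistatic variance
  is detectable by a non-linear kernel only when the number of interacting
  pairs is small relative to the training records; with hundreds of pairs
  and a few hundred records the epistatic term is statistically
  indistinguishable from noise for every model and the comparison is
  uninformative.
* Network-vs-gBLUP on additive signal: 150 loci, 200 hybrids, fractions
  0.8 additive / 0.2 residual, a 5-configuration random search over the
  desk-scale space with 40-epoch budgets, 5 final replicates.
* Bandwidth recovery at $h^\star = 1$: $n = 300$, ten feature dimensions,
  signal-to-noise 4:1. Variance-proportion recovery: 500 hybrids, additive
  proportion 0.5, single linear kernel.
* Monte-Carlo validation of the arc-cosine kernel: $2\mathbb{E}[\mathrm{relu}(w\cdot x)\,
  \mathrm{relu}(w\cdot x')]$ over $10^6$ standard-normal draws shared
  across the 55 entry checks; because the 55 standardized errors are
  correlated standard normals, the test admits the binomially plausible
  number of 3-standard-error exceedances rather than demanding all 55
  simultaneously (a ~14% false-alarm design under a correct kernel), with
  a hard 5-SE ceiling.

## Numerical choices

* GWAS marker selection uses the spectral single-random-effect mixed model:
  variance components estimated once per environment on the null model by
  a maximum-likelihood profile over the kinship eigenbasis, then per-marker
  generalized least squares at those components; per-locus p-values are
  combined over the environments where the locus was polymorphic using
  Fisher's method with a $10^{-300}$ floor against $\log 0$. A fixed,
  configurable number of kinship principal components (default 0) replaces
  stepwise covariate selection, which is not the analysis target here.
* Monomorphic loci are dropped with a warning before coding; coding a
  locus at frequency 0 or 1 is an error, not a silent zero column.
* Zero-variance feature columns are dropped (with a warning) during
  train-statistics standardization; test rows never contribute to the
  statistics.
* Dunnett comparisons use the classical equal-variance form through
  `multcomp`; replicate seeds make homoscedasticity approximately true.
  One-sided alternatives follow the metric: greater for correlation, less
  for RMSE. Per-environment metrics require at least 3 test records.
* MSE decomposition uses $1/n$ standard deviations so the three components
  sum to the MSE exactly; the correlation term is defined as 0 when either
  standard deviation vanishes.

## Limitations

The sampler covers Gaussian likelihoods and the whole-kernel prediction
scheme only; no sparse or approximate eigendecompositions are provided
(the exact dense route is intended for data that fit in memory, with the
interface leaving room for an approximate backend); the network engine is
CPU-bound and deliberately small — it exists to make the tuning protocol
and the model comparison executable and testable, not to compete with GPU
frameworks at production scale.
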
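---
title: "histomix: model, assumptions and design choices"
author: "histomix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{histomix: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

histomix partitions a spatially resolved transcriptomics (SRT) tissue
section into *histology-based spatial domains*: clusters of spots that
are coherent both in gene expression and in the cell-type composition
visible in the matched histology image. It then tests every gene for
domain-specific differential expression. The package works from three
profiles:

* **Molecular profile** `Y` (`N x P'`): a low-dimensional representation
  of expression. Counts `c_ij` are divided by the per-spot total
  `s_i = sum_j c_ij`, log-transformed with a pseudocount of 1
  (`log(c_ij / s_i + 1)`; zero-safe and monotone), restricted to the top
  `n_top = 2000` most variable genes, and reduced by PCA to `P' = 3`
  components. More components buy little on typical sections and
  inflate the parameter count.
* **Image profile** `V` (`N x Q`): counts of AI-classified nuclei by
  cell type, one row per spot. Each nucleus is assigned to the nearest
  spot center, i.e. a spot's "expanded area" is its Voronoi cell; this
  tiles the section, so every cell is counted exactly once even though
  capture spots cover only part of the tissue. Any segmentation /
  classification tool can produce the input table (`cell_id, x, y,
  cell_type`); histomix never touches image files.
* **Geospatial profile** `G` (`N x N`): binary spot adjacency, built by
  thresholding Euclidean distance. With the automatic threshold (1.2x
  the minimal nonzero spacing, robust to coordinate jitter) interior
  spots have 4 neighbors on square/grid lattices and 6 on the
  triangular lattices used by hexagonally packed platforms.

Imaging-based, single-cell-resolution data are binned onto a manually
added square grid (half-open `[a, b)` intervals on both axes, 0-based
unit indices, so a cell on a grid line lands in exactly one unit);
molecular values are normalized, transformed and reduced per cell and
then averaged within each occupied unit, cell types are counted per
unit, and adjacency is rook (4-neighbor).

# Stage I: normal-multinomial mixture with an MRF prior

Each spot `i` carries `x_i = {y_i, v_i}`. Given the domain label
`z_i = k`:

* `y_i ~ MN(mu_k, Sigma_k)` — a multivariate normal sub-component for
  the molecular profile;
* `v_i ~ Multinomial(m_i, omega_k)` with `m_i = sum_q v_iq` — a
  multinomial sub-component for the image profile, where `omega_k` (a
  point on the Q-simplex) is the domain's underlying cell-type
  composition and the quantity of primary biological interest.

The two modalities come from different measurement processes and are
treated as conditionally independent. The mixture component is

```
f_k(x_i) = MN(y_i; mu_k, Sigma_k) * Multi(v_i; m_i, omega_k)^w
```

where `w` in `[0, 1]` tempers the image profile's contribution. At
`w = 0` the image profile is ignored entirely; `w = 0.05` is a good
default for spot-level platforms (where `m_i` is large and the
multinomial term would otherwise dominate the three PC dimensions) and
`w = 0.5` for grid-binned single-cell data. A spot with `m_i = 0`
contributes no multinomial term.

Spatial smoothness enters through a Markov random field (Potts) prior
on the labels:

```
pi(z_i = k | z_-i) ∝ exp(d_k + f * sum_{i'} g_{ii'} I(z_{i'} = k))
```

with offsets `d_k = 1` and smoothness `f = 1` by default. Larger `f`
gives smoother domain maps but risks the Potts phase transition (all
spots collapsing into one domain), so `f` should not be pushed far
above 1 blindly.

## Priors and conjugate updates

* `mu_k | Sigma_k ~ MN(nu0, Sigma_k / tau0)` with `nu0` the empirical
  mean of `Y` and `tau0 = 0.01`, so the data dominate the domain means.
* `Sigma_k ~ IW(eta0, Phi0)` with `eta0 = P' + 1`, `Phi0 = I`.
* After PCA the score columns are orthogonal, so the default covariance
  model is **diagonal**: per component,
  `mu_kp | sigma2_kp ~ N(nu0_p, sigma2_kp / tau0)` and
  `sigma2_kp ~ IG(0.1, 0.1)` (a standard weakly informative choice).
  `covariance = "full"` switches to the full MN-IW treatment.
* `omega_k ~ Dirichlet(alpha0)` with `alpha0 = 1/2`.

All four updates are conjugate and available in closed form; the
posterior hyperparameters follow the usual Normal-Inverse-Wishart /
Normal-Inverse-Gamma and Dirichlet algebra, and the package exposes
them (`conjugatePosterior`, `omegaConcentration`) so tests can verify
them symbolically.

Two notational wrinkles deserve a note. First, in the diagonal variant
we keep the normal prior mean `nu0` and the inverse-gamma shape as
separate quantities (`igShape`, `igRate`); the posterior mean of
`mu_kp` is the precision-weighted average
`(tau0 nu0_p + n_k ybar_kp) / (tau0 + n_k)`, which collapses to the
data mean as `tau0 -> 0` and to `nu0` as `tau0 -> Inf`. Second, when
`w < 1` the tempered likelihood implies a tempered composition update,
`alpha_kq = alpha0_q + w * sum_{i: z_i = k} v_iq`; this is the default
because it keeps the Gibbs sampler's conditionals consistent with one
joint tempered posterior. `temperedOmega = FALSE` reproduces the
untempered update `alpha_kq = alpha0_q + sum v_iq`; the two coincide at
`w = 1`.

## Gibbs sampler

Each sweep updates all `z_i` in index order (log-space computation with
max-subtraction before normalizing the K conditional probabilities),
then `(mu_k, Sigma_k)` and `omega_k` for every domain. Defaults are
2000 sweeps with the first 1000 discarded. Labels are initialized by
k-means on the standardized `Y` concatenated with standardized
cell-type proportions (a deterministic function of the seed; uniform
random fallback if k-means fails); parameters are first drawn from
their conditionals given that initialization.

All randomness flows through three independent `mt19937_64` streams
(labels / normal-component parameters / compositions) derived from one
integer seed. Chains are therefore exactly reproducible, and a chain
that never consults the image profile consumes the same label and
parameter streams as a `w = 0` chain — the two are identical draw for
draw, which the test suite checks directly.

## Label switching

Mixture likelihoods are invariant under permutation of the component
indices, so raw draws wander between the `K!` equivalent labelings. We
impose an order restriction on a reference cell type `q_ref` (by
default the type with the largest global cell count): every stored draw
is permuted, jointly over `(z, mu, Sigma, omega)`, so that
`omega[, q_ref]` is strictly decreasing in the domain index, ties
breaking by original index. Domain 1 is then always the domain richest
in the reference type. The restriction only identifies the labels when
the domains genuinely differ in the reference type's abundance; when
two domains tie on every candidate type, no ordering can separate them
and composition summaries for those domains will mix.

## Point estimates, uncertainty and interactive zones

Marginal probabilities `pi(z_i = k | .)` are label frequencies across
the stored draws; `zhat_i` is the row-wise argmax (ties to the lowest
index). A spot where no domain reaches 0.9 is a *boundary spot*; an
argmax tie implies a maximum of at most 0.5, so tied spots are always
boundary spots. Connected components of boundary spots under `G` of
size at least two are the *interactive zones* (connectivity via
igraph); isolated boundary spots are reported separately rather than
silently dropped, since a single ambiguous spot is more often noise
than a zone.

Compositions are summarized by posterior means and equal-tailed sample
quantile credible intervals; arbitrary posterior probabilities such as
`pi(omega_kq > omega_k'q | .)` are draw-wise indicator averages
(`compositionProb`).

## Choosing K

The integrated completed likelihood is

```
ICL(K) = -2 log L(Y, V, zhat | plug-in estimates) + d log(N),
d = 2 K P' + K (Q - 1)
```

with the complete-data likelihood evaluated at the modal labels and
posterior-mean parameters, and the recommended `K` its argmin
(`selectK`). When `K` exceeds the true number of domains the surplus
components duplicate an existing domain, the order restriction cannot
stabilize them, and the plug-in estimates average over switching draws;
the likelihood term then collapses and overfitted `K` is penalized
sharply. That behavior is convenient for selection but means ICL
*differences* above the selected `K` should not be over-interpreted.

# Stage II: spaDEG detection

For a target domain `k`, each gene is fitted with a negative binomial
regression `c_ij ~ NB(s_i * lambda_ij, psi_j)` on the binary indicator
`x_i = I(zhat_i = k)` via `MASS::glm.nb`, with `log(s_i)` as offset.
Because `x` is binary, the log-link model is an exact reparameterization
of the additive mean model `lambda = alpha + beta x` with the same null
hypothesis `beta = 0`, while keeping the mean positive; the literal
additive form is available behind `link = "identity"` (fitted by direct
maximum likelihood, since a multiplicative size factor under an
identity link is not a glm offset). The default test is the Wald z-test
on `beta`, with a likelihood-ratio option. p-values are adjusted by
Benjamini-Hochberg; genes with adjusted p below 0.05 are spaDEGs.
All-zero genes are skipped and non-converged fits are excluded from the
BH family, with counts reported.

## Size factors

Stage I normalizes by raw per-spot totals, and `normalization =
"total"` reproduces that choice in Stage II. It is not the default,
for a measurable reason: when a minority of genes is strongly
domain-enriched, the totals absorb that enrichment, so the offset
carries a domain-correlated bias (~8% in log units in our default
calibration conditions) that shifts *every* null gene's estimate and
inflates the type-I error and FDR well beyond nominal. The default is
therefore a median-of-ratios size factor (per spot, the median ratio of
counts to per-gene geometric means, computed over positive counts and
rescaled to geometric mean one) followed by one refinement pass that
re-estimates the size factors from the genes the first pass did not
flag and refits. The refinement matters because with noisy per-gene
counts the contamination is not an outlier tail that a median or a
trimmed mean can reject — it acts as a small location shift — whereas
removing *detected* spaDEGs restores the "most genes are not DE"
assumption directly. Under a global null the first pass flags
essentially nothing and the refinement is a no-op.

## Diagnostics

`spotRichness` returns the per-spot fraction of genes with nonzero
counts (with optional group summaries, e.g. interactive zone vs other
boundary spots). `moransI` computes the classical spatial
autocorrelation statistic with binary adjacency weights,

```
I = (N / S0) * sum_{ii'} g_{ii'} (x_i - xbar)(x_{i'} - xbar) / sum_i (x_i - xbar)^2,
```

returning `NA` with a warning for constant input. A perfect
checkerboard on a lattice gives exactly -1 and the permutation null has
mean `-1/(N-1)`; both are verified in the tests.

# The synthetic data generator

`simulateDataset` draws every observable of the generative model the
two stages assume: a square or triangular lattice; a true partition
(contiguous vertical blocks by default, or a Potts draw at a chosen
interaction strength via `pottsPartition`); per-spot cell totals
`m_i ~ Poisson(20)`; cell-type counts `v_i ~ Multinomial(m_i,
omega*[z_i])`; molecular values `y_i ~ MN(mu*[z_i], Sigma*[z_i])`; and
NB gene counts with designated spaDEG genes shifted by a chosen
log-fold-change in one domain.

Default conditions (chosen once as a strong but non-degenerate signal
that runs in seconds): 20x20 lattice, `K = 3`, `Q = 4` cell types,
dominated compositions with cell type 1's abundance strictly decreasing
across domains (0.7 / 0.4 / 0.1) so the relabeling order restriction
identifies every domain, molecular means separated by 2.5 at unit
variance, NB baseline mean 5 with dispersion (size) 2, 200 null + 50
shifted genes at log-fold-change 1, and per-spot depths
`s_i ~ logNormal(0, 0.2)`.

What the generator does **not** emulate: histology images or nuclei
segmentation/classification error (cell types are drawn exactly from
the domain composition), platform-specific artifacts (spot swapping,
diffusion between spots), per-gene mean-variance trends, or
between-sample batch structure. Passing the recovery and calibration
checks on this generator therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not robustness
to the many ways real sections violate them.

# Numerical choices and conventions

* All mixture arithmetic is in log space; conditional label
  probabilities are normalized after max-subtraction.
* PCA component signs are fixed (largest-magnitude loading positive) so
  results do not depend on the linear algebra backend.
* Highly variable gene ranking breaks ties by gene index (stable sort).
* Inverse-Wishart draws use the Bartlett decomposition; Dirichlet draws
  use normalized gammas with a hard floor at 1e-300 to avoid degenerate
  zeros at tiny concentrations.
* An empty domain's parameter updates fall back to the prior, so the
  sampler tolerates transiently empty domains without special casing.
* Spots with zero total counts are dropped from all profiles jointly;
  spots with zero cells are retained (their multinomial term is
  vacuous).

# Problem sizes used by the checks

The test suite and acceptance script run the full pipeline on the
default 20x20 fixture (2000 sweeps; about 2 s per fit), select `K` over
2..6, and calibrate Stage II on 1000 null genes x 200 spots — sizes
chosen so a complete run finishes in a few minutes on one core while
leaving Monte-Carlo error well inside the tolerances being checked.

# Known limitations

* Cell-type abundance is assumed homogeneous within a domain; tissues
  with smooth composition gradients will be cut into bands rather than
  tracked continuously.
* `K` is fixed per fit; selection is by refitting over a grid rather
  than a nonparametric prior.
* The MRF prior's normalizing constant is intractable, so `f` is fixed
  rather than estimated; the default `f = 1` is conservative with
  respect to the phase transition.
* Stage II treats the Stage-I labels as known; label uncertainty is not
  propagated into the DE test (boundary spots can be excluded by the
  caller as a sensitivity check).
* Single-sample only; no joint multi-section model.
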
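# histomix

Histology-integrated Bayesian spatial domain detection for spatially
resolved transcriptomics (SRT).

## The problem

Spot-level SRT platforms measure expression on a lattice of capture
spots, each mixing several cells, while the matched H&E image carries
single-cell morphology that standard expression-only clustering
ignores. histomix is for analysts who have (a) a spot-by-gene count
matrix with spot coordinates and (b) a table of AI-classified nuclei
(`cell_id, x, y, cell_type`) from any segmentation/classification tool,
and who want tissue domains that are coherent in *both* modalities,
with uncertainty, plus the genes that mark each domain.

## The model

**Stage I.** Each spot `i` carries a low-dimensional expression vector
`y_i` (top `P' = 3` PCs of normalized, log-transformed counts) and a
cell-type count vector `v_i` (nuclei in the spot's Voronoi "expanded
area"). Given its domain `z_i = k`,

    y_i ~ MN(mu_k, Sigma_k)
    v_i ~ Multinomial(m_i, omega_k),   m_i = sum_q v_iq

and the mixture component is `MN(y_i; mu_k, Sigma_k) * Multi(v_i; m_i,
omega_k)^w`, with `w` in `[0, 1]` weighting the image modality. A Potts
/ Markov random field prior `pi(z_i = k | z_-i) ∝ exp(d_k + f *
sum_{i'} g_{ii'} I(z_{i'} = k))` on the spot adjacency graph `G`
encourages spatially smooth domains. Conjugate priors
(Normal-Inverse-Wishart or per-PC Normal-Inverse-Gamma; Dirichlet on
`omega_k`) give a closed-form Gibbs sampler (implemented in C++),
label switching is resolved by ordering domains on a reference cell
type's abundance, and the number of domains is selected by the
integrated completed likelihood `ICL(K) = -2 log L + (2KP' + K(Q-1))
log N`. Spots whose maximum marginal probability stays below 0.9 are
boundary spots; their connected components are *interactive zones*.

**Stage II.** For a target domain `k`, every gene is tested with a
negative binomial regression `c_ij ~ NB(s_i lambda_ij, psi_j)` on the
binary indicator `x_i = I(zhat_i = k)` (log link, `log(s_i)` offset,
Wald test, Benjamini-Hochberg correction): significant genes are
domain-`k`-specific spaDEGs. Per-spot expression richness and Moran's I
are provided as diagnostics.

A synthetic-data module (`simulateDataset`) draws full datasets from
exactly this generative model, so every claim the package makes is
testable without downloads.

## Worked example

```r
library(histomix)

sim <- simulateDataset(simulationSpec(nGenesNull = 1000, seed = 42))
sim$image
#> ImageProfile: 400 spots x 4 cell types ( 7854 cells )
#>   types: type1, type2, type3, type4

chain <- fitDomains(sim$molecular, sim$image, sim$geo, K = 3, w = 1,
                    nIter = 2000, burnIn = 1000, seed = 42)
call <- callDomains(chain)
call
#> DomainCall: 400 spots, 3 domains
#>   boundary spots: 3 ( threshold 0.9 )
#>   interactive zones: 1 ( + 1 singletons )

head(estimateComposition(chain), 4)
#>   domain cell_type       mean     ci_low   ci_high
#> 1      1     type1 0.69028812 0.67148834 0.7100261
#> 2      1     type2 0.09850781 0.08618549 0.1115903
#> 3      1     type3 0.10672056 0.09356356 0.1197095
#> 4      1     type4 0.10448351 0.09196230 0.1169397

mclust::adjustedRandIndex(domainLabels(call), sim$trueZ)
#> [1] 1

deg <- fitSpaDEG(sim$counts, call, domain = 1)
sum(deg$spadeg)        # 50 genes were truly shifted in domain 1
#> [1] 51
head(deg[order(deg$p_adj), c("gene", "beta", "psi", "p_adj")], 3)
#>          gene     beta      psi        p_adj
#> 1033 gene1033 1.189676 2.067388 3.779205e-43
#> 1046 gene1046 1.112436 2.219839 2.004490e-40
#> 1019 gene1019 1.013268 2.155292 1.284340e-36
```

Domain 1 is the domain richest in the reference cell type (here type1,
true abundance 0.7, estimated 0.690 with a tight credible interval);
the modal labels reproduce the generative partition exactly (adjusted
Rand index 1), three ambiguous spots form one interactive zone plus a
singleton, and the domain-1 test recovers the 50 shifted genes (51
discoveries, estimated shifts near the true log-fold-change of 1).

A command-line driver with the same functionality is installed at
`system.file("scripts", "histomix", package = "histomix")`, with
subcommands `simulate | prepare | fit | select-k | spadeg |
diagnostics`; each run writes its effective configuration and seed to a
JSON manifest next to its outputs.

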
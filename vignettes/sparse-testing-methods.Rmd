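---
title: "Sparse testing for genomic prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse testing for genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseMET)
```

## The problem

A multi-environment trial (MET) that grows every breeding line in every
environment spends most of its plots re-measuring lines it has already
measured elsewhere. Sparse testing phenotypes each line in only a subset of
environments and predicts the unobserved line-by-environment cells from
marker data. Two questions drive the design of such a program: *which lines
should go where* (the allocation problem), and *how should the unobserved
cells be predicted* (the modelling problem). sparseMET implements both, plus
the machinery to evaluate them: a two-stage analysis pipeline, a
cross-validation harness, a cost-benefit calculator, and a synthetic-data
generator with known truth.

## The two-stage analysis

Stage one summarizes plot-level data within each environment into genotype
BLUEs. For an alpha-lattice (replicates subdivided into incomplete blocks)
the model is

$$y_{irk} = \mu + R_r + B_{k[r]} + G_i + e_{irk},$$

with replicate $R_r$ and genotype $G_i$ fixed and the incomplete block
$B_{k[r]}$ random, $B_{k[r]} \sim N(0, \sigma^2_{B(R)})$. `fit_stage_one()`
estimates the variance components by REML (via `lme4::lmer`) and then
computes genotype adjusted means and standard errors by generalized least
squares at those estimates; the weight carried forward is $1/\mathrm{SE}^2$,
the standard inverse-variance weighting for two-stage analyses. Non-positive
variance estimates are clamped to $10^{-8}$ with a warning, and confounded
genotype/replicate designs are rejected with the aliased terms named.
Trials analysed with other first-stage models (e.g. spatially adjusted
row-column designs) enter the pipeline as externally computed BLUE tables —
the second stage only needs the tidy (line, environment, trait, value,
weight) records.

## The genomic model

Stage two is the multi-trait GBLUP with genotype-by-environment (G$\times$E)
interaction fitted by `sparse_gblup()`:

$$Y = 1_n\mu^\top + X_E \beta_E + Z_L g + Z_{EL}\, g_E + \epsilon,$$

where $Y$ is $n \times n_T$ (cells ordered by environment then line),
$\beta_E$ are fixed environment effects, and

* $g \sim MN_{J \times n_T}(0,\, G,\, \Sigma_T)$ — line main effects, with
  $G$ the VanRaden genomic relationship matrix and $\Sigma_T$ the genetic
  trait covariance;
* $g_{E,i} \sim MN_{J \times n_T}(0,\, G,\, \Sigma_{T2})$ independently per
  environment $i$ — the interaction effects. Under one-hot environment
  design matrices this block-diagonal form is exactly the Hadamard-product
  covariance $(Z_E Z_E^\top \odot Z_g G Z_g^\top)$ of the interaction term;
* residual rows iid $N(0, R)$, optionally scaled per cell by stage-one
  weights.

With a single trait the covariances collapse to scalars and the model is
the uni-trait GBLUP with G$\times$E. A design mask (from the allocation
module) marks the testing cells; they are treated as missing.

### Sampler

All full conditionals are standard, so the model is fitted by Gibbs
sampling:

1. missing cells are imputed from their conditional normal given the
   observed traits in the same row (data augmentation);
2. environment effects have flat priors and normal full conditionals;
3. $g$ is sampled jointly across lines and traits by rotating into the
   eigenbasis of $G$ (computed once) and a trait basis that jointly
   diagonalizes $R$ and $\Sigma_T$, reducing the update to independent
   scalar draws; the same machinery updates each environment's $g_{E,i}$;
4. $\Sigma_T$, $\Sigma_{T2}$ and $R$ have inverse-Wishart full
   conditionals.

With heterogeneous weights the rotated system is no longer diagonal in the
line dimension and the update falls back to a dense $J \times J$ Cholesky
solve per trait component — exact, but intended for the moderate $J$
typical of weighted stage-two analyses.

### Priors and defaults

The quantities a user must choose are deliberately few:

* **Priors**: inverse-Wishart with $\nu = n_T + 4$ degrees of freedom and
  scale set so each component's prior expected variance is one quarter of
  the observed phenotypic variance per trait; flat priors on $\mu$ and
  $\beta_E$. This mimics the variance-partitioned weak defaults common in
  genomic prediction software; with $n$ in the hundreds the likelihood
  dominates.
* **MCMC**: 10,000 iterations, 2,000 burn-in, thinning 5 by default. The
  models mix quickly because $g$ and $g_E$ are sampled jointly; the
  validation suite uses shorter chains (stated below) with
  Monte-Carlo-error-aware tolerances. Batch-means MC standard errors of the
  variance components are reported by `summary()`.
* **Identifiability**: $1_n\mu^\top$ and $X_E\beta_E$ are jointly
  unidentified, so the sampler works with per-environment intercepts and
  reports $\mu$ as their mean and $\beta_E$ as deviations.
* **Numerical safeguards**: $G$ is ridge-regularized
  (`regularize_psd()`, eigenvalue floor $10^{-6}$ times the mean diagonal)
  before factorization — genomic relationship matrices are routinely
  singular when lines outnumber effective markers; covariance draws are
  symmetrized; a NaN in the chain aborts with the iteration index.

## Allocation methods

Four strategies build the $J \times I$ training mask, from the notation
$k = \lceil Jr/I \rceil$ lines per location and $N = Jr = Ik$ total plots:

* **M1** phenotypes a random fraction of lines in *all* environments; the
  rest are never observed. Simple, but testing lines get no phenotypic
  connection to any environment.
* **M2** keeps a shared core as M1 and splits the testing lines into $I$
  near-equal slices (remainders round-robin to the first environments),
  phenotyping slice $i$ in environment $i$ only, so every line is observed
  somewhere.
* **M3** fills environments sequentially with $k$ lines drawn uniformly
  among lines still below $r$ appearances, topping up from minimal-count
  lines when fewer than $k$ remain eligible (ties broken uniformly). Column
  sums are exactly $k$; row sums are $r \pm 1$.
* **M4** pursues the balanced-incomplete-block ideal: all pairs of lines
  co-occurring within environments equally often. Exact BIBDs rarely exist
  for arbitrary $(J, I, k)$, so M4 runs a steepest-descent exchange search
  from M3 starts: swap a line out of and into an environment whenever that
  strictly lowers the variance of the off-diagonal concurrence counts
  $\Lambda = MM^\top$, never widening the replication spread, best of
  `n_restarts` random starts. The search is monotone by construction and
  finds classical BIBDs when they exist (e.g. $J = I = 7$, $k = r = 3$,
  $\lambda = 1$); `concurrence()` exposes $\Lambda$ and the balance score
  for any design.

Cross-validation requests fractions while M3/M4 are parameterized by $r$;
the mapping $r = \mathrm{round}(f \cdot I)$ clamped to $[1, I-1]$ is used,
so the attainable fractions are multiples of $1/I$. This mapping is a
package choice — the methods' sources never state one.

A practical caution the package's own tests surfaced: at $r = 1$ the M3/M4
masks are *disconnected* (no line pair spans two environments), and
environment contrasts are then identified only through the genomic prior.
Accuracy at very sparse settings depends on this connectivity at least as
much as on the allocation method — which is exactly the argument for the
concurrence-balancing of M4.

## Evaluation

`run_cv()` redraws, for every method $\times$ testing-fraction $\times$
partition, a fresh allocation (partition seeds derived from one master
seed via a counter scheme), fits the model on training cells only, and
scores the masked cells per trait with the Pearson correlation and the
NRMSE, $\mathrm{RMSE}/|\bar y_{obs}|$ (range normalization is available for
responses centered at zero). Metrics are pooled across environments within
a trait; partition means (the APC) and SDs are appended. A failed fit in
one partition is recorded as missing and the run continues. Testing cells
never inform the fit: the acceptance suite corrupts them and verifies
bitwise-identical predictions.

## Cost-benefit arithmetic

`evaluate_scenario()` reproduces the standard-versus-sparse comparison for
a fixed plot budget: at training fraction $f$ the same
$\mathrm{plots} = \mathrm{trts} \times \mathrm{locs}$ budget accommodates
$\mathrm{round}(\mathrm{plots}/(\mathrm{locs} \cdot f))$ treatments at $f$
replicates per location. Percentage gains are computed from the integer
treatment counts — and, for plots per (new) line, from the unrounded plot
ratios — then rounded to two decimals; "plots per treatment" is computed as
plots per *new* line, so that the quantity measures what the budget buys in
untested material rather than in repeated checks. One guarded failure mode
is unreachable by construction: with $f \le 1$ a sparse design always keeps
at least as many treatments as the standard, so the treatment count can
never fall below the check count; the guard remains for defensive use.

## The synthetic-data generator

`sim_markers()` draws per-marker allele frequencies uniformly (default
0.05–0.5) and dosages Binomial(2, $p_j$) — an unstructured panel with no
linkage disequilibrium, stratification or QTL architecture. Passing tests
on such panels therefore demonstrates correctness of the machinery, not
performance on structured breeding germplasm, where relatedness typically
*helps* prediction. `sim_phenotypes()` forward-simulates exactly the model
the sampler fits, with variance components expressed as proportions of a
unit phenotypic variance (`h2`, `prop_ge`, remainder residual) so that
configurations read as heritabilities; matrix-normal effects are drawn via
Cholesky factors of the regularized $G$ and the trait covariances, and
environment means default to $N(0,1)$ draws — the scale of environment
contrasts in yield-type traits relative to unit genetic variance.
`sim_plot_data()` wraps genotype truth in an alpha-lattice-like layout for
stage-one testing.

## Validation study sizes

The shipped validation suite (and the reproduction script
`scripts/acceptance.R`) uses these deliberately desk-scale configurations:

* sampler-versus-closed-form: $J = 100$, $I = 3$, one trait, fixed variance
  components, no interaction — the posterior mean of $g$ must match the
  mixed-model-equations solve within Monte Carlo error (3 batch-means SEs);
* parameter recovery: ten replicates at $J = 200$, $I = 3$, $n_T = 2$,
  genetic correlation 0.7, $h^2 = 0.5$ — posterior trait correlation and
  genomic variance proportion within $\pm 0.15$ of truth in at least 8;
* multi- versus uni-trait: $J = 150$, correlation 0.8, M3 at 50% testing,
  10 partitions — multi-trait APC within 0.02 of (in practice above) the
  uni-trait APC;
* accuracy versus sparsity: $J = 300$, $h^2 = 0.6$, M1 at 15% versus 85%
  testing — the APC drop stays below 0.15, the qualitative robustness that
  motivates sparse testing in the first place;
* concurrence balance: M4 at or below M3's balance score averaged over 100
  seeds at $J = 8$, $I = 4$, $r = 2$.

Chain lengths in these checks (1,200–4,000 iterations) are shorter than the
fitting defaults; the tolerances above were chosen for those lengths via
the reported MC standard errors.

## Known limitations

* The sampler is data-augmentation based: heavily sparse masks slow the
  mixing of effects for never-observed lines (their draws random-walk
  through the imputed cells). The eigenbasis updates keep this acceptable
  at the package's intended scale ($J$ up to a few thousand, $n_T$ small).
* Heterogeneous residual weights use one weight per line-by-environment
  row (averaged across traits if the table differs by trait), preserving
  the matrix-variate structure.
* The first stage covers replicate/incomplete-block models only; spatial
  (e.g. AR1$\times$AR1) adjustments should be done in specialized software
  and their BLUEs imported.
* Marker input is plain dosage CSV; no VCF/PLINK readers, and no
  dominance or epistatic kernels.
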
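---
title: "Estimating and imputing cis haplotype associated RNA expression"
author: "hare package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and imputing cis haplotype associated RNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hare)
```

## The problem

In inbred crop panels genotyped through a haplotype graph, every line
carries one founder haplotype ID per genic *reference range*. Measured RNA
expression at a gene mixes a *cis* part, attributable to the haplotype the
line carries at the gene itself, with a genome-wide *trans* part and
noise. The cis part — the **haplotype associated RNA expression (HARE)** —
is the transferable quantity: once a per-haplotype effect is estimated in
one panel, it can be imputed into any other panel that carries the same
founder haplotypes, including lines and tissues in which expression was
never measured. The imputed values then serve as features for
whole-genome regression on complex traits.

This vignette documents the models, the algorithmic and numerical choices,
the synthetic-data generator used for validation, and the limits of what
the accompanying tests demonstrate.

## Per-gene variance partition

For one gene with expression vector $y$ over $n$ lines, three nested
models are available:

1. $y = 1\mu + Z_{cis}\alpha + e$ — cis haplotype effects fixed;
2. $y = 1\mu + u_{cis} + e$ — cis effects random,
   $u_{cis}\sim N(0, H_{cis}\sigma^2_{cis})$;
3. $y = 1\mu + u_{cis} + u_{trans} + e$ — adds
   $u_{trans}\sim N(0, H_{trans}\sigma^2_{trans})$.

$Z_{cis}$ is the $n \times p$ indicator matrix of the gene's haplotypes;
$H_{cis} = Z_{cis}Z_{cis}^\top / (\mathrm{tr}(Z_{cis}Z_{cis}^\top)/n)$ is
the trace-normalized cis haplotype relationship matrix, and $H_{trans}$
the analogous kernel built from the column-concatenated indicators of
*all* genic ranges. Trace normalization fixes $\mathrm{tr}(H) = n$ so
variance components live on the scale of $y$.

From a model-3 fit, the decomposition reports
$h^2_{cis} = \sigma^2_{cis}/\sigma^2_{tot}$,
$h^2_{trans} = \sigma^2_{trans}/\sigma^2_{tot}$, the heritable proportion
$(\sigma^2_{cis}+\sigma^2_{trans})/\sigma^2_{tot}$ and the cis share of
heritable variance $\sigma^2_{cis}/(\sigma^2_{cis}+\sigma^2_{trans})$,
with $\sigma^2_{tot}=\sigma^2_{cis}+\sigma^2_{trans}+\sigma^2_e$.

Design choices worth stating explicitly:

* **$H_{trans}$ includes the focal gene's own range.** The trans kernel is
  "combined across all genes"; with hundreds of ranges the focal
  contribution is negligible, and including it keeps one kernel shared by
  every gene (a large saving). `buildTransHRM(excludeRange=)` provides the
  leave-one-out variant for sensitivity analysis.
* **Lines with a missing haplotype at the focal range are dropped** from
  that gene's fit rather than imputed; genotype imputation is upstream of
  this package. Mean imputation enters only at the HARE-matrix stage,
  where unobserved haplotypes receive the gene's mean estimated effect.
* **Model-1 identifiability** is resolved by grand-mean centering: $\mu$
  is the unweighted mean of $y$ and $\alpha_h$ the carrier-group mean
  minus $\mu$. Under unbalanced designs the effects therefore do not sum
  to zero when weighted by carrier counts.

## REML

Variance components are estimated by restricted maximum likelihood with
the error variance profiled out analytically, leaving only variance
*ratios* to optimize:

* **Model 2** (one ratio): after rotating by the eigendecomposition of
  $H_{cis}$, each evaluation of the restricted likelihood is $O(n)$; the
  profile is maximized over $\log\gamma \in [-25, 25]$ by golden-section
  search with explicit endpoint checks, since the profile can be monotone
  (boundary optimum, variance floored at zero).
* **Model 3** (two ratios): Nelder–Mead on
  $(\log\gamma_{cis}, \log\gamma_{trans})$ from five spread starts
  (relative tolerance $10^{-12}$, 400 iterations each, best kept).
  Each evaluation needs $W^{-1}$ for
  $W = \gamma_c H_{cis} + \gamma_t H_{trans} + I$. Two routes give
  identical likelihoods: a dense Cholesky ($O(n^3)$, any kernels), and a
  fast route used by the per-gene drivers that exploits
  $\mathrm{rank}(Z_{cis}) = p \le$ number of founders: with the trans
  kernel eigendecomposed once per panel, the Woodbury identity reduces an
  evaluation to $O(np^2)$. The test suite asserts the two routes agree.
* Variances are reported as zero when the optimizer rests at the lower
  ratio bound ($e^{-29}$); a near-collinear kernel pair
  (correlation of off-diagonals > 0.99) is flagged `identifiability` —
  the total genetic variance is then identified but its split is not.

## HARE extraction and imputation

The random-effect models are written at line level, so a haplotype-level
estimate is obtained by the BLUP projection
$\hat a = \sigma^2_a Z^\top V^{-1}(y - 1\hat\mu)$ with
$\sigma^2_a = \sigma^2_{cis}/c$, $c = \mathrm{tr}(ZZ^\top)/n$ and $V$ the
fitted marginal covariance. Because $H_{cis} = ZZ^\top/c$, this is the
unique haplotype vector whose line-level image satisfies
$\hat u_{cis} = Z\hat a$ exactly (an identity the tests assert to
$10^{-8}$). As shrinkage vanishes ($\sigma^2_{cis}/\sigma^2_e \to
\infty$, balanced design) $\hat a$ converges to the model-1 group-mean
effects; at $\hat\sigma^2_{cis}=0$ it is identically zero.

HARE values are stored as effects *relative to* the per-gene intercept
$\hat\mu_g$; imputation re-adds $\hat\mu_g$, so imputed matrices live on
the expression scale and are directly comparable (and correlatable) with
measured expression. Imputation is a deterministic lookup:
$\mathrm{value}(i, g) = \hat\mu_g + \hat a_{g, h(i,g)}$, with the gene's
mean estimated effect substituted for missing calls and mean-imputed
haplotypes, and a hard error for haplotype IDs outside the training
universe.

Multi-tissue integration is the element-wise mean or maximum over
per-tissue matrices; transferability is summarized by per-gene Pearson
correlations across lines, over all unordered tissue pairs (21 pairs for
7 tissues).

## Genomic prediction

Ridge regression solves
$\hat\beta = \arg\min_\beta \|y - X\beta\|_2^2 + \lambda\|\beta\|_2^2$
in closed form via one thin SVD of the standardized design (centered,
unit variance, intercept unpenalized) — which is simultaneously the
$n < p$ dual solution. Predictions are invariant to affine rescaling of
any feature column; $\lambda$ is interpreted on the standardized scale,
which is why the default grid spans $[10^{-4}, 10^4] \times p$
($p \approx \mathrm{tr}(X^\top X)/n$ after standardization), 100
log-spaced points.

$\lambda$ is chosen by $k$-fold cross-validation (default 10) minimizing
mean held-out squared error, with ties resolved toward heavier
shrinkage. A tie is defined at the resolution of the CV estimate itself:
any $\lambda$ whose curve value lies within one fold-standard-error of
the minimum (the familiar 1-SE rule). On a pure-noise response the error
curve is flat beyond full shrinkage and exact floating-point ties never
occur; without the 1-SE band the selected $\lambda$ would be an
essentially arbitrary point of the flat region. $\lambda$ is re-selected
inside every training split, never using test data.

Two evaluation protocols mirror common practice:

* **within-panel** — repeated random 80/20 sub-sampling validation,
  20 repeats by default, per-repeat Pearson accuracy between observed and
  predicted trait values;
* **cross-panel** — train in one panel, test in another sharing the
  founder haplotypes; with a family map, 20 stratified training subsets
  (10 lines per family, i.e. 250 lines for a 25-family panel) are
  averaged; lines present in both panels are removed from the test set
  first.

One master seed expands deterministically into split, fold, subset and
permutation seeds, making every protocol reproducible bit for bit.

## The random-HARE baseline

Haplotype sharing alone carries predictive signal, so accuracy gains must
be measured against a baseline that preserves haplotype *structure* while
destroying effect *labeling*: per gene, the haplotype-to-effect map is
shuffled uniformly over the haplotypes present, independently across
genes and permutation replicates. Lines sharing a haplotype still share
the permuted value, and each gene keeps its exact multiset of effects.
All $k$ permuted runs (default $k = 100$) reuse the observed run's exact
train/test partitions, so the comparison isolates the labeling.
Significance is the Monte Carlo estimate $p = (r+1)/(k+1)$, with ties
counting toward $r$ (conservative); the smallest attainable $p$ is
$1/(k+1) = 1/101$.

Note that with few haplotypes per gene the baseline is strong: a permuted
encoding of a 5-level partition retains much of a cis-driven signal,
because regression can partially relabel it. The separation between HARE
and random HARE grows with the richness of the allelic series — which is
the scientific point of the comparison.

## The synthetic-data generator

The simulator provides panels with the statistical structure the
estimators assume, so the full workflow is testable without external
data:

* **Founders**: 26 founders by default, one designated common parent;
  haplotype ID = founder index at every range, so all derived panels
  share one universe.
* **NAM-design panel**: 25 biparental families × 200 RILs by default.
  Recombination is a two-state Markov chain along the ordered ranges of a
  single linear genome with switch probability
  `crossoversPerRangeSet/(nRanges-1)`; a fair start keeps the marginal at
  1/2 per parent. Lines are fully homozygous (one ID per range). This
  reproduces the design's diversity numbers: median haplotype frequency
  100 and median plug-in entropy
  $-(0.5\ln 0.5 + 25 \cdot 0.02 \ln 0.02) = 2.30$ nats.
* **Diverse panel**: each line a mosaic of founder haplotypes with
  geometric block lengths and uniform founder draws — a structural
  stand-in for a diverse association panel, *not* a population-genetic
  model of any real panel.
* **Expression**: per gene and tissue,
  $y = \mu_g + Z_g a_g + w_t + e$. Cis effects $a_g$ are drawn iid per
  haplotype and shared across tissues; the trans value $w_t$ is a random
  projection of all *other* genes' haplotype indicators (so its
  covariance structure matches what $H_{trans}$ models) with tunable
  cross-tissue correlation; $e$ is iid. Each realized component is
  rescaled to the scenario's exact target variance — cis
  $= \texttt{cisShare}\times h^2$, trans $= (1-\texttt{cisShare})\times
  h^2$, error $= 1-h^2$ — so realized variance shares meet their targets
  by construction rather than only in expectation. The default scenario
  pins `cisShare = 1/3` and `heritability = 0.55`, the regime of cis
  shares and expression heritabilities typical of diverse maize panels.
  The generative ledger ($\mu_g$, $a_g$, per-line cis and trans values)
  is kept in the object metadata for oracle tests.
* **Traits**: weighted sums of causal genes' true cis values plus noise
  with SD `traitNoise` × SD(genetic signal), so the trait heritability is
  $1/(1+\texttt{traitNoise}^2)$. The same causal architecture can be
  re-expressed on any panel sharing the founders, which is what makes
  honest cross-panel experiments possible.

What the generator does **not** emulate: real recombination maps and
chromosome structure, selection, residual heterozygosity, non-Gaussian
expression (counts, zero inflation, library-size effects), upstream
normalization artifacts, cis–trans interaction, and enhancer–tissue
interaction. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every property of
real RNA-seq data.

## Validation sizes and numerical tolerances

The test suite validates, at sizes chosen to keep a laptop run
comfortable: variance-component recovery on 100 genes × 400 lines
(medians within ±0.10 of the targets); the BLUP projection identity to
$10^{-8}$; model-2 REML against a dense grid-search oracle within one
grid step on 20 instances of $n \le 50$; the closed-form ridge against a
gradient-descent oracle to $10^{-6}$; permutation calibration on 200 null
traits at $k = 100$ (Kolmogorov–Smirnov distance from uniform < 0.1, with
model-1 HARE refit per replicate so the exchangeability argument is
exact); and the cross-panel ordering HARE > random HARE on 20 scenario
replicates (25 families × 20 RILs, 30 genes, training subsets of 250,
tested on a 260-line diverse panel). Kernel algebra (trace = $n$,
symmetry, PSD) is asserted to $10^{-9}$, decomposition identities to
$10^{-12}$, TSV round trips to $10^{-12}$.

## Known limitations

* Standard errors of variance components and of HARE effects are not
  computed; the permutation baseline is the only inferential tool.
* The REML surface for model 3 can be flat when the cis and trans kernels
  are similar (small panels, long mosaic blocks); the `identifiability`
  flag marks, but does not fix, such fits.
* The trans kernel treats all non-focal genes exchangeably; explicit
  regulator architecture (hub genes, networks) is out of scope.
* Dosages are inbred-style {0, 2}; heterozygotes are tolerated with a
  warning but no dominance modeling exists.
* LD pruning is a deterministic greedy left-to-right scan with a trailing
  window; other implementations visiting sites in a different order will
  retain a different (equally valid) site set.
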
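---
title: "Inferring the allelic series at a QTL: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the allelic series at a QTL: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlseries)
```

## The problem

In a multiparental population (Collaborative Cross, DSPR, MAGIC and
relatives), each individual's genome is a mosaic of `J` founder haplotypes.
At a detected QTL the standard analysis fits one additive effect per founder
haplotype. That model implicitly assumes all `J` haplotypes are functionally
distinct, which is rarely realistic: haplotypes typically group into
`K <= J` *functional alleles*. The assignment of haplotypes to alleles —
the **allelic series** — is the object this package infers, jointly with the
allele effects, from a phenotype vector and (possibly uncertain) diplotype
state probabilities.

## The model

Writing `D` for the `N x (J + J(J-1)/2)` diplotype indicator matrix, `A` for
the additive map from diplotype states to haplotype half-counts, and `M` for
the `J x K` allelic series matrix,

$$ y \mid D, M, \beta_{alle}, \sigma \sim N(D A M \beta_{alle},\ \sigma^2 I_N). $$

The allele effects are reparameterized as an intercept plus independent
effects through a `K x (K-1)` orthonormal sum-to-zero contrast basis `C`
(normalized Helmert contrasts; any orthonormal sum-to-zero basis gives the
same likelihood): $\beta_{alle} = \mu 1 + C\beta$. Conjugate priors

$$ \sigma^{-2} \sim \mathrm{Ga}(\tfrac{\kappa}{2}, \tfrac{\lambda}{2}), \quad
   \mu \mid \sigma \sim N(0, \sigma^2\tau^2), \quad
   \beta \mid \sigma, \phi \sim N(0, \sigma^2\phi^2 I_{K-1}) $$

let `(\mu, \beta, \sigma)` be integrated out analytically, leaving a
multivariate-t *collapsed likelihood* `p(y | D, M, phi)` that can be
evaluated for any series, of any dimension, at `O(N K^2 + K^3)` cost via
low-rank determinant and inverse identities (the `N x N` covariance is never
formed). This is what makes partition-space posterior sampling practical.

By default the error and intercept priors are taken at their improper limits
(`kappa = lambda = 0`, `tau = Inf`), encoded as explicit sentinels in
`series_hyper()`. Because the intercept prior scales with `sigma`, the
`tau -> Inf` limit keeps exponent `N/2` on the profiled quadratic form and
normal-gamma shape `N/2`; the collapsed value is then defined up to one
additive constant shared by every series and every `phi` at fixed data, so
differences — which is all the sampler and the Bayes factors use — are
exact. A fully proper path (finite `kappa`, `lambda`, `tau`) is retained and
is used by the prior-sampling validation tests.

The relative allele-effect scale `phi` (so that
`h2_QTL = phi^2 / (phi^2 + 1)` is the prior proportion of variance explained)
gets a half-t prior with `v = 2` degrees of freedom. We note in passing that
the induced prior density on `h2_QTL` at `v = 2` is proportional to
`h^{-1/2} (2-h)^{-3/2}`: it is not globally monotone decreasing (it has a
shallow dip at `h = 0.5`), but its mode is at zero and it strongly favors
small effects; larger `v` increases shrinkage.

## Priors over the allelic series

**CRP.** The default prior over partitions is the Chinese restaurant process
with density
$\Gamma(\alpha)\Gamma(\alpha+J)^{-1}\alpha^K\prod_k\Gamma(J_k)$, whose
concentration parameter `alpha` gets a `Gamma(a_alpha, b_alpha)` prior. The
default rate is *elicited*: `elicit_b_alpha(J, 1, 0.5)` solves for the rate
that puts 50% of the marginalized prior mass on the one-allele (null)
series — approximately 2.33 at `J = 8`. The elicitation integral
`E_alpha[prod_j j/(alpha+j)]` is computed by quantile-transform quadrature
split at fixed quantiles of the gamma prior, which is accurate from
`b_alpha = 1e-9` to `1e9`.

**Tree-informed prior.** The CRP is exactly the partition distribution
induced by Poisson functional mutations (rate `0.5 alpha` per coalescent
unit) on a random Kingman coalescent tree of the founders. When a local
phylogeny is available the integral over trees is dropped:
`tree_partition_prior()` enumerates all `2^{2J-2}` branch mutation
configurations, maps each to the series it implies (two leaves share an
allele iff no mutated branch lies on the path between them), and accumulates
probabilities. The mutation rate is marginalized *exactly* against its gamma
prior using an inclusion–exclusion closed form over mutated branches,
evaluated for all configurations at once by a signed superset (Moebius)
transform over branch bitmasks in `O(n 2^n)` with `n = 2J - 2`; the
alternating scalar sum is accumulated in extended precision because its
terms are `O(1)` while the result can be small. Both routes are validated
against adaptive quadrature in the test suite. Enumeration is refused above
`J = 12` (the space is astronomically large for, e.g., `J = 15`; use the
CRP there). Multiple trees (e.g. a posterior sample from a phylogenetics
run) are handled by averaging the per-tree priors.

Branch lengths are used exactly as given, in coalescent units; no height
normalization is applied, and a warning is emitted for non-ultrametric
input. Non-binary trees are rejected rather than silently resolved.

**Variant-consistent restriction.** `restrict_prior()` keeps only series
that refine the distinctions implied by a known causal variant — useful for
connecting series inference to candidate variants.

## Posterior inference

`series_fit()` runs a partially collapsed Gibbs sampler with four steps per
iteration:

1. **Series update (collapsed).** Each haplotype's allele assignment is
   resampled conditional on the others, with `(\mu, \beta, \sigma)`
   integrated out — weights are collapsed likelihood times the CRP
   conditional prior (or the marginal tree-prior table, treated as
   exchangeable, with the sweep order freshly randomized each iteration to
   avoid order bias). Under the CRP the concentration parameter is then
   refreshed by the standard two-step beta/gamma-mixture latent update,
   which depends only on `K` and `J`. Collapsing matters because `beta`
   changes dimension with `K`; the effects are redrawn immediately after,
   so no stale coefficient is ever read.
2. **Effects and error scale (joint).** `(\mu, \beta, \sigma^{-2})` are
   drawn exactly from their conjugate normal-gamma conditional.
3. **Effect scale.** The half-t prior on `phi` factors into two
   conditionally conjugate latents, `phi = |eta| sqrt(psi)`: `psi` is
   inverse-gamma given the effects, and `eta` is normal given the data —
   a parameter-expansion move that jointly rescales `(phi, beta)` and mixes
   well near `phi = 0`.
4. **Diplotype states (joint).** Each individual's state is drawn
   independently from likelihood times its prior probability row; when all
   rows are point masses (states known) this step is skipped.

Initialization: the one-allele series (tree mode: the highest-prior series),
per-individual prior-argmax diplotypes, `phi = 0.5`, `alpha` at its prior
mean. Burn-in defaults to 10% of the run. All draws come from R's seeded
RNG, so a fit is bit-reproducible given `seed`.

The whole state reduces to `J`-dimensional Gram matrices, so iteration cost
is essentially independent of `N`; the collapsed-likelihood kernels are
compiled (RcppArmadillo) with a pure-R reference implementation kept and
tested for exact agreement.

Correctness of the sampler is established by marginal-conditional (Geweke)
comparison on a small proper-prior problem — prior draws versus successive
conditional draws must agree in distribution for every statistic — and by
prior-recovery runs at `phi = 0`, where the likelihood is flat in the series
and the partition chain must be stationary at its prior table.

## Marginal likelihood and Bayes factors

`marginal_likelihood()` implements a Chib-style estimator at the ordinate
`(M*, phi*)` (MAP series; posterior-median `phi` from a reduced run):

$$ \log m(y) = \log p(y \mid M^*, \phi^*) + \log p(M^*) + \log p(\phi^*)
             - \log p(M^* \mid y) - \log p(\phi^* \mid M^*, y). $$

`p(M*|y)` is the chain's posterior frequency; `p(phi*|M*,y)` is a
Rao–Blackwell average, over one reduced run with the series fixed at `M*`,
of the one-dimensional conditional `p(phi | beta, sigma)` normalized by
quadrature on a log grid. The likelihood ordinate is exact when diplotypes
are known and a Monte-Carlo prior average otherwise. Under the improper
defaults the estimate carries an unknown constant common to all models with
the same individuals and flat block; `bayes_factor()` checks that signature
before differencing, so only well-defined comparisons (allele-based vs the
haplotype-based "Full" model, vs the null, between prior choices) are
possible. On fixed-series models the estimator collapses to quantities that
can be checked against one-dimensional quadrature, which anchors its
correctness in the tests (agreement well within 0.02 in log).

## The synthetic-data generator

`simulate_qtl()` implements the evaluation protocol end to end: a Kingman
coalescent tree over the founders (uniform pair merges, `Exp(k(k-1)/2)`
waiting times); an allelic series drawn from `p(M | T, alpha)` restricted to
a target `K`; a balanced, homozygous, known-diplotype design; `K` *equally
spaced* allele effects centered and scaled so their population variance
(denominator `K`) equals the QTL effect size `h2`; and a standard normal
error vector exactly centered and rescaled to population variance `1 - h2`.
Defaults are `J = 8`, `N = 400`, `alpha = 1`, matching a Collaborative
Cross-sized experiment. Equal spacing avoids arbitrarily small,
undetectable allele differences at large `K`; the population-variance
denominator is our reading of the recipe (the alternative `K-1` denominator
changes effects by a factor `sqrt((K-1)/K)`). With balanced haplotypes but
unbalanced allele sizes the individual-level genetic variance can differ
slightly from `h2`; that is faithful to the literal recipe.

Tree misspecification for robustness studies comes in two strengths:
`"incorrect"` replaces the tree with an independent coalescent draw, and
`"partial"` applies one random nearest-neighbor interchange and redraws all
node times from the Kingman distribution in a random topology-compatible
order. The partial procedure is a labelled approximation — the original
procedure it stands in for is not fully specified in the source literature.

What the generator does **not** emulate: heterozygous or uncertain
diplotypes (real reconstructions are probabilistic), population structure
and kinship, replicate observations, dominance, multi-QTL architectures,
and non-normal phenotypes. Passing recovery tests therefore demonstrates
correctness of the inference machinery under the stated generating model,
not robustness to those real-data complications.

## Problem sizes used by the tests

The recovery study in the test suite and acceptance script runs the
biallelic case exactly at the protocol's experiment size — `K = 2`,
`h2 = 0.5`, `N = 400`, 50 replicates, 5,000 Gibbs iterations per fit —
where MAP accuracy above 0.9 and the effect-MSE ordering
`Known <= CRP <= Full` are expected; the saturated case (`K = 8`, 30
replicates, 3,000 iterations) exhibits the reversed `CRP > Full` ordering,
the known cost of shrinking toward few alleles when every haplotype is
distinct. Distributional oracle checks use 20,000 coalescent trees (CRP
identity), 200 random quadrature cases (tree prior), and 20,000-iteration
Geweke runs. Real analyses should use longer chains (the protocol's
reference analyses used 100,000 iterations); stable results are often
obtained with a tenth of that.

## Numerical choices and edge cases

- All probability tables are kept in log space internally; partition keys
  are restricted-growth strings (`"0,1,0,1,1,0,0,0"`).
- `phi = 0` and `K = 1` are handled as exact degenerate cases (effect block
  dropped), not by small-number fudging.
- A zero-length branch can never be mutated, so its indicator carries no
  mass; zero-variance phenotypes raise an explicit degenerate-rate error.
- The diplotype-state categorical draws use the Gumbel-max trick on the
  log-posterior matrix, vectorized over individuals but order-stable for
  reproducibility.
- Canonical branch ordering (for aligning mutation indicator vectors) is
  depth-first from the root with children ordered by their clade's smallest
  founder label.

## Limitations

Tree-informed priors require a rooted binary coalescent-scaled tree of the
founders at the QTL, which is itself uncertain in recombinant material;
averaging over a tree sample is supported, but joint inference over trees
is not. The exhaustive branch-configuration enumeration limits tree-informed
priors to `J <= 12`. Bayes factors under improper priors are only defined
between models sharing the flat block. Kinship/polygenic background,
dominance and replicate designs are out of scope.
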
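---
title: "Phylogenetic regression of gene copy number: models, simulations, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic regression of gene copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnpgls)
```

## The scientific problem

Across mammals, body size and lifespan vary over orders of magnitude while
cancer prevalence does not track either trait (Peto's paradox). One
candidate mechanism is gene copy-number change: duplication of tumor
suppressors or immune genes could offset the extra cancer risk of being
large and long-lived. `cnpgls` provides the comparative machinery to test
this idea when the data are (i) an ultrametric species tree, (ii) an
orthogroup × species copy-number matrix, (iii) per-species life-history
values and necropsy-derived cancer phenotypes, and (iv) gene-set
definitions keyed to a reference species' gene symbols.

Species are not independent observations: closely related species share
both genome content and phenotypes by descent. Every test in this package
is therefore a *phylogenetic* regression.

## The PGLS model

For response $y$ (a phenotype over $n$ species), design matrix $X$
(intercept, copy-number predictor, covariates), the model is

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\left(0,\; \sigma^2 \,
   D^{-1/2} V(\lambda)\, D^{-1/2}\right), $$

where $V(\lambda)$ is the Brownian-motion covariance of the tree (entry
$(i,j)$ = root-to-MRCA shared path length) with off-diagonals multiplied by
Pagel's $\lambda \in [0,1]$, and $D = \mathrm{diag}(w)$ holds observation
weights. $\lambda = 0$ recovers (weighted) OLS, $\lambda = 1$ pure Brownian
residuals. $\lambda$ is profiled by bounded ML on $[0,1]$ (tolerance
$10^{-6}$); coefficient tests are two-sided $t$ with $n-p$ degrees of
freedom, ignoring the uncertainty in $\hat\lambda$ (the convention of the
comparative-methods packages this mirrors).

Numerically, the weighted lambda family factorizes as
$C(\lambda) = \tilde W^{1/2}\,(\lambda K + (1-\lambda)I)\,\tilde W^{1/2}$
with $K$ the Brownian *correlation* matrix (weight-independent) and
$\tilde W$ diagonal. One symmetric eigendecomposition of $K$ per
tree-and-weights combination makes each profile evaluation $O(np)$, which
is what lets the per-orthogroup screens and the 1,000-replicate nulls run
in seconds (`pgls_structure()` is reused across fits).

**Weights.** A species with weight $w$ has residual variance scaled by
$1/w$; cancer phenotypes use $w = \sqrt{\text{necropsies}}$ so that
prevalence estimates resting on few examined animals are down-weighted.
Only relative weights matter (doubling all weights changes nothing, a
tested invariant). Whether the upstream package the convention mirrors
weights variances or standard deviations is not documented; this package
commits to the variance convention and isolates it in one place
(`design_spec()`).

**Model recipes.** Body-size models use log body mass as response with log
longevity as covariate, and vice versa (each life-history trait adjusts
the other); both always include a proteome-size covariate to absorb
annotation-depth differences between genomes. Cancer-phenotype models use
the necropsy weights and, by default, only the proteome covariate. The
per-orthogroup screen uses total proteome size; the gene-set screen uses
the count restricted to reference-annotated orthogroups, because sets are
defined by reference symbols and only annotated sequences can belong to
one. Copy-number predictors enter untransformed.

**Degenerate inputs.** Orthogroups whose count is constant over the
aligned species produce a rank-deficient design; such rows are kept in the
output flagged `testable = FALSE` and excluded from the BH family size,
so the accounting of every screen is reproducible. A failed Cholesky gets
one jitter of $10^{-10}\cdot\mathrm{tr}(C)$, then errors.

## The aggregate gene-set test

For a gene set, the per-species predictor is the summed copy number over
the set's orthogroups (each orthogroup counted once even if several of its
symbols are members — double counting would silently inflate aggregates).
The same weighted $\lambda$-PGLS applies. The point of the test: many
individually undetectable per-gene effects of consistent sign accumulate
in the aggregate. BH adjustment is applied across sets; Bonferroni and
Hommel family-wise adjustments are reported alongside for the strictest
claims.

## Robustness nulls

Two simulation nulls probe a significant set:

* **Variance-matched random sets** — each replicate replaces every target
  orthogroup by one drawn from the same cross-species-variance decile
  (deciles over all filtered orthogroups, targets excluded from the pool,
  no replacement within a replicate). "Similar variance" has no stated
  tolerance in the source analysis; per-gene decile matching is the
  recorded choice. Within a decile the variance distribution is still
  long-tailed, so sampling prefers candidates within a 30% log-variance
  window (falling back to the 5 nearest); without this the replicate mean
  variance systematically overshoots targets in the top decile.
* **Brownian phenotype** — the observed aggregate is held fixed and the
  response replaced by Brownian draws on the tree ($\sigma^2$ scaled to
  unit tip variance at mean depth, root 0 — cosmetic, since PGLS p-values
  are scale invariant).

Both record the replicate p-values of the aggregate term and are
bit-reproducible given a seed. `empirical_p()` uses the $(r+1)/(n+1)$
convention so that no empirical p-value is exactly zero.

## The reversed Poisson model

Counts-as-response is modelled as a log-link Poisson regression with
phylogenetic dependence treated as a GEE working correlation (the
$\lambda$-transformed Brownian correlation). A single phylogeny is *one*
correlated cluster, so the usual cluster-robust sandwich estimator is
rank-one and meaningless; standard errors are model-based GEE errors
scaled by the Pearson dispersion, and the `method` tag on the fit records
this so alternative estimators can be compared. On a star tree (or with
$\lambda = 0$) the estimating equations reduce exactly to ordinary Poisson
IRLS, a tested equivalence.

## Enrichment analyses

The screen's per-orthogroup results feed two standard competitive tests.
The two-group-then-rank recipe (genes split by association sign, each
group ordered by p-value) is formalized as the score
$\mathrm{sign}(\hat\beta)\cdot(-\log_{10} p)$, which yields the identical
order as a single total order; ties break by $|\hat\beta|$ then symbol,
and $p = 0$ is replaced by the smallest representable positive with a
warning. GSEA uses the classic (unweighted) enrichment statistic — the
extremum of the hit/miss running sum — with gene-label permutation,
sign-matched normalization, and BH within each direction. ORA is the
one-sided hypergeometric tail against the *testable* background (all genes
mapped to screened orthogroups), not the whole genome: enrichment must be
judged against what could have been called.

## The synthetic-data generator

Grading a pipeline like this needs data with known truth. The generator
emulates the statistical structure the method relies on, not the biology
that produces it:

* **Tree** — pure-birth, rescaled to unit height, 94 tips by default.
* **Copy numbers** — per orthogroup, a log-normal base abundance
  (`base_sdlog = 1`, spreading per-orthogroup variances over >2 orders of
  magnitude, which the variance-decile matching needs), a latent Brownian
  log-abundance on the tree (rate `dispersion = 0.3`), and Poisson counts.
  This yields integers, tree correlation, and heteroskedasticity — the
  three properties the tests exercise. A birth–death gene-count process
  would add realism but nothing testable.
* **Phenotypes** — $\lambda$-structured Brownian latents; log body size
  and log longevity share variation through an allometric slope (0.25);
  neoplasia prevalence and malignancy rate pass latents through a logistic
  link (baselines 0.30 and 0.40); necropsies are uniform on 20–80
  ("tens of individuals"); neoplasm and malignant-case counts are nested
  binomials, so the count invariants hold by construction.
* **Planted effects** — a set's centred aggregate count enters the target
  phenotype's latent linearly. Planted sets are drawn from the middle
  (40–60th percentile) variance band of filter-surviving annotated
  orthogroups so the signal is distributed across members rather than
  dominated by one high-variance gene — the regime the aggregate test is
  for, and the pattern of the published 12-gene worked example (per-gene
  $|t|$ between about 1.5 and 3.7, none individually significant).

Two planted effect sizes are used by the acceptance tests and were frozen
before the tests were finalized: 0.04 per aggregate-count unit (the
"weak-per-gene / detectable-aggregate" regime) and 0.10 (the "strong"
regime in which the observed p-value falls below every replicate of both
nulls).

**What a green test does not establish.** The generator's counts are
conditionally Poisson around a smooth latent; real orthogroup tables carry
annotation artifacts (fragmented models, collapsed paralogs) with
non-Poisson error. Phenotype registries have far more heterogeneous
sampling than uniform 20–80 necropsies. And synthetic "mouse" symbols are
one-to-one with orthogroups, so annotation ambiguity is untested.

## A calibration caveat worth knowing

With binomially sampled proportions as the response (malignancy rate on a
few dozen animals), the weighted Gaussian PGLS p-values are well behaved
in the bulk (null rejection fractions near nominal) but *anticonservative
in the far tail*: in null simulations at a family of ~1,000 orthogroups,
the probability of at least one BH discovery is roughly 0.2 rather than
0.05. The cause is heteroskedastic binomial noise — species with very few
observed neoplasms produce outlying rates that the $\sqrt{\text{necropsy}}$
weighting does not fully capture — interacting with high-leverage,
long-tailed count predictors. For a correctly specified continuous trait
the same screen is calibrated (P(any BH discovery) ≈ 0.05). The package's
type-I/FDR acceptance test therefore uses the longevity screen; the
cancer-phenotype screens' bulk behavior is still covered by the rejection-
fraction bracket. Users screening registry-derived proportions should
treat isolated extreme p-values with corresponding caution — which is
precisely what the two robustness nulls are for.

## Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `min_frac` (orthogroup filter) | 0.5, strict | fraction of species | zeros are indistinguishable from annotation dropout; "more than half nonzero" read literally, exactly half is excluded |
| $\lambda$ search | $[0,1]$, tol $10^{-6}$ | — | boundary ties report the boundary |
| weights | $\sqrt{\text{necropsies}}$ | — | measurement-reliability convention; variance scale |
| `dispersion` | 0.3 | latent BM rate | sets tree correlation and count spread |
| `base_sdlog` | 1.0 | log counts | >2 orders of magnitude of per-orthogroup variance |
| `necropsy_range` | 20–80 | animals | tens-of-individuals registry scale |
| `n_perm` (GSEA) | 10,000 | permutations | default where none is stated |
| ORA background | testable genes | — | competitive tests must condition on testability |

## Known limitations

* No OU or early-burst correlation structures; $\lambda$-BM only.
* REML is not offered; $\lambda$ is profiled by ML per fit (per
  orthogroup, per set), never shared across fits.
* The PGLM's working-correlation $\lambda$ is fixed (default 1), not
  estimated from Pearson residuals.
* Polytomies are accepted as-is; covariance math handles them via path
  sums, but no attempt is made to resolve them.
* Ultrametricity is a warning, not an error: downstream math does not
  require it, and published time trees routinely fail exact checks by
  rounding.
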
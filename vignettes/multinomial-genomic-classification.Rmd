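---
title: "Multinomial genomic classification with probit threshold models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multinomial genomic classification with probit threshold models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoclass)
```

## The problem

Many categorical traits in animal and plant breeding — breed or
subpopulation membership, coat colour, discrete anatomical types — have no
meaningful ordering of their classes, so ordinal threshold models do not
apply. genoclass treats the K-class prediction problem as a collection of
binary contrasts between classes, fits each contrast with a Bayesian probit
threshold model on genome-wide SNP covariates, and reassembles the binary
outputs into a single vector of multinomial class probabilities. The same
machinery yields measures of divergence between subpopulations (fixation
indices, eigenvector-inclusion complexity, liability-scale heritability of
class membership) and multinomial breeding values (expected offspring
fractions per class).

## The binary threshold model

Each binary contrast is modelled through a latent liability

$$ l = W b + Z u + e, \qquad e \sim N(0, I), $$

with the observed class indicator `y = 1` exactly when the liability
exceeds a threshold:

$$ \Pr(y = 1 \mid \eta) = \Phi(\eta - \delta), \qquad \eta = W b + Z u. $$

Two constraints make the model identifiable: the residual variance is fixed
at 1 (all variance components are therefore on the liability scale) and the
threshold is fixed at $\delta = 0$ while an intercept column is carried in
`W` — the standard equivalent parameterization of estimating a single free
threshold.

Fitting is by data augmentation Gibbs sampling: liabilities are drawn from
normals truncated at 0 on the side dictated by the class label
(inverse-CDF sampling, with the uniform deviate clamped to
$[10^{-12}, 1 - 10^{-12}]$ and the draw clamped to $\pm 8$ standard units
around its mean), location effects from Gaussian full conditionals, and
variance components from scaled-inverse-chi-square full conditionals.

Three marker-effect priors are available:

* **ridge** — $u_j \sim N(0, \sigma^2_u)$ with a single common variance;
  the GBLUP-equivalent model.
* **bayes_a** — a variance per marker,
  $\sigma^2_j \sim \chi^{-2}(\nu, S)$, marginally a scaled-t prior.
* **bayes_c_pi** — a spike-slab: each marker is included with probability
  $\pi$, $\pi \sim \mathrm{Beta}(1, 1)$, with indicators sampled with the
  effect integrated out of the likelihood ratio.

### Why the ridge effects are updated as one block

Single-site Gibbs updates of hundreds of correlated marker effects mix
catastrophically slowly in one particular direction: the overall scale of
the genetic values. In our diagnostics a chain on 200 markers sat at
var(Zu) ≈ 3.5 for 400,000 iterations while an independently coded
block-update sampler (and the likelihood itself) supported values near 9.
The package therefore draws the whole ridge effect vector from its joint
multivariate-normal full conditional in every iteration, which costs only
O(m·r) after a one-time thin SVD of `Z` (components along the right
singular vectors have precision $s_k^2 + 1/\sigma^2_u$; null-space
components are prior draws). BayesA and BayesC-pi keep single-site updates
because their per-marker variances and indicators require them; their main
use here is on near-orthogonal eigenvector designs, where single-site
updates are effectively independent.

### Prior scale heuristic

The scaled-inverse-chi-square prior on $\sigma^2_u$ uses `df_u = 5` and a
scale chosen so the prior mode of the genetic variance
$\sigma^2_u \cdot \sum_j \mathrm{var}(z_j)$ matches $R^2/(1-R^2)$ with a
default expected $R^2 = 0.5$ — i.e. the prior expects features to explain
half the liability variance. This mirrors the default prior specifications
of the standard whole-genome-regression software in this field. For
BayesC-pi the slab scale is doubled (the prior mean of $\pi$ is 0.5, so
half the features are expected to carry the variance). Both `df_u` and the
target `r2` (or an explicit `scale_u`) are exposed in
`threshold_model_spec()`.

Posterior predictive probabilities are Monte-Carlo averages of
$\Phi(w'b + z'u)$ over all kept samples — not $\Phi$ evaluated at the
posterior-mean linear predictor, which would be overconfident.

## From binary to multinomial

With classes $C_1, \dots, C_K$:

* **One-vs-all (OVA)**: K classifiers, class k against the rest. Class
  probabilities are the normalized binary success probabilities
  $p_k = \Pr_k / \sum_l \Pr_l$. OVA contrasts are almost always unbalanced
  (the complement is K−1 times larger); the package warns when the positive
  class falls below 20 %.
* **One-vs-one (OVO)**: K(K−1)/2 classifiers, each trained only on its two
  classes. Two combination rules are provided:
  * *voting*: $p_k = \frac{2}{K(K-1)} \sum_{k' \ne k} c_{kk'}$ with
    $c_{kk'} = 1$ when $p_{kk'} > p_{k'k}$ — a counting measure over
    pairwise winners;
  * *pairwise coupling*: the pairwise probabilities should satisfy
    $p_{kk'} = p_k / (p_k + p_{k'})$; summing over $k'$ yields the
    stationarity system $p = Qp$ with $Q_{kk'} = p_{kk'}/(K-1)$ off the
    diagonal and $Q_{kk} = \sum_{l \ne k} p_{kl}/(K-1)$, solved under
    $p_k > 0$, $\sum p_k = 1$. When the table is consistent the true
    simplex vector is recovered exactly (this inversion property is tested
    against a constrained least-squares solver over thousands of random
    simplex points). Entries are clipped to $[10^{-6}, 1-10^{-6}]$ first —
    the fixed point needs interior entries. The solver is a direct
    normalized linear solve with a power-iteration fallback
    (tolerance $10^{-10}$, 10,000 iterations cap).

Ties in the final argmax break to the lowest class index, with a warning.
An OVO sample from a class no binary machine was trained on is still
scored by every pairing; coupling absorbs the inconsistency, and voting is
available separately.

Any binary classifier can be plugged in through the backend registry
(`register_backend()`): a backend must train on a feature matrix and
produce either probabilities (usable everywhere) or discrete labels
(usable in OVO voting only). The built-in max-margin backend is a thin
adapter over the libsvm-backed `e1071::svm()` with library-default tuning
and a linear kernel, used exactly in that label-only role.

## Multinomial breeding values

For a selection candidate with gene content $z_n$ and a base population
with allele frequencies $f$ and class fractions $p_0$, the expected
fraction of offspring in class k is

$$ p_{n_k} = \frac{\Phi(\bar w' b_k + 0.5\,(z_n - 2f)' u_k - \delta_k)}
                  {\sum_l \Phi(\bar w' b_l + 0.5\,(z_n - 2f)' u_l - \delta_l)}, $$

using the K one-vs-all effect vectors: the candidate transmits half of its
centered genotype to offspring whose other gamete comes from the base
population. The 0.5 factor is applied exactly as written. Effect vectors
enter at their posterior means — the formula is defined with point
vectors, and averaging the ratio over the posterior would define a
different (and less interpretable) estimand. The breeding value is
$g_n = p_n - p_0$, which sums to zero by construction.

## Evaluation

Prediction accuracy uses leave-one-out cross-validation: with strongly
unbalanced classes, leaving out one individual maximizes the number of
training samples while preserving the data structure in every fold. The
package retrains from scratch in every fold and recomputes marker-centering
frequencies on the training fold only, so no information from the held-out
individual leaks into the features. Metrics:

* **Accuracy** — correct classifications over total classifications;
* **Brier score** — $N^{-1} \sum_i \sum_j (p_{ij} - [y_i = j])^2$, from 0
  (perfect) to 2 (always confidently wrong);
* **scaled Brier score** — $sBS = 1 - BS/BS_{\text{baseline}}$ against the
  uniform baseline $p_{ij} = 1/K$ (whose Brier score is exactly
  $(K-1)/K$); 0 means no better than uniform random assignment, 1 perfect,
  negative worse than the baseline. A class-frequency baseline is exposed
  as an option; the uniform baseline is the default. Per-class sBS uses
  the same uniform baseline restricted to that class's samples.

Full-length chains (30,000 iterations, 15,000 burn-in — the package
defaults) are unnecessary inside every LOO fold; CV defaults to 2,000
iterations with 500 burn-in, which our simulations show is ample for the
posterior-predictive class probabilities (the quantity CV needs), and a
full-length spec can be passed explicitly.

## Population-divergence statistics

**Pairwise F_ST.** Per marker, the package computes Weir–Cockerham-style
allele-count moment components: the between-class mean square MSP, the
within-class mean square MSG, and the effective allele count $n_c$, giving
$\theta = (\mathrm{MSP} - \mathrm{MSG})/(\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG})$.
This convention equals 1 at opposing fixation, ~0 for equal class
frequencies, and — unlike the plain ratio of the between-class frequency
variance to $\bar p (1 - \bar p)$, which is exposed as
`convention = "wright"` but biased toward F/2 for two classes — recovers
the generative Balding–Nichols divergence parameter without bias. The
dataset-level `estimate` is the standard multilocus ratio of sums, which
our simulations show is unbiased across F ∈ {0.01, …, 0.2}; `mean`/`sd`
summarize the per-marker values (clamped below at 0).

**Global F_ST.** Per marker, gene content is modelled by a linear mixed
model (REML via lme4) with a random subpopulation effect. Because gene
content sums two alleles, its between-class variance is $4\,\mathrm{Var}(p)$
while its residual is twice the per-allele sampling variance; the reported
index converts back to the allele-frequency scale as
$\sigma^2_\alpha / (\sigma^2_\alpha + 2 \sigma^2_\epsilon)$. Gene content
is fitted raw (0/1/2), not standardized.

**Eigenvector inclusion (pEV/nEV).** For two classes, the genomic
relationship matrix of their samples is eigendecomposed and class
membership is regressed on the eigenvectors under the BayesC-pi probit
model. The posterior mean of $\pi$ is pEV; nEV = pEV·(N−1). Strongly
diverged pairs need a single eigenvector (low pEV); admixed pairs need
many. The last eigenvector is dropped (centered G has rank N−1) along with
any numerically null ones. Eigenvectors enter **unscaled**: with
eigenvalue-scaled columns, near-null eigenvalues give columns of vanishing
norm whose indicators the data cannot identify, and the posterior of $\pi$
collapses to its prior (we measured pEV ≈ 0.49 on a fully diverged
two-population simulation under scaling, against 0.03 unscaled —
only the latter matches the expectation that one eigenvector suffices).
`scaling = "sqrt_eigenvalue"` restores the genetic-value-scale variant.

A caveat established during validation, and confirmed with an independent
JAGS implementation of the same spike-slab probit: with N samples and N−1
eigenvector covariates the design is saturated, so under *random* labels
the model can and does assign nonzero inclusion to some eigenvectors —
the likelihood gain from separating arbitrary labels outgrows the
spike-slab's complexity penalty. pEV contrasts between class pairs are
informative; absolute inclusion probabilities under label noise are not
calibrated null hypotheses tests.

**Heritability of subpopulation assignment.** For a class pair, a probit
animal model is fitted with the Cholesky factor of either the genomic or
the pedigree relationship matrix as the random-effect design, and
$h^2 = \sigma^2_a/(\sigma^2_a + 1)$ with the residual fixed at 1. Values
near 1 mean class membership is almost fully explained by (genomic or
pedigree) relationships.

## The synthetic-population simulator

`simulate_population()` emulates the structure of a multi-breed
genotyping study:

* K subpopulations diverge from ancestral allele frequencies
  $p \sim U(0.05, 0.95)$ under the Balding–Nichols model,
  $p_k \sim \mathrm{Beta}(p(1-F)/F,\, (1-p)(1-F)/F)$, so the expected
  between-population frequency variance at a marker is $F\,p(1-p)$;
* markers are unlinked — the methods in this package operate on
  relationship and allele-frequency structure, which Balding–Nichols
  captures; linkage disequilibrium is deliberately not simulated, so
  passing tests say nothing about LD-driven effects in real data
  (marker-density requirements, within-family prediction from
  co-segregation);
* optional half-sib families: shared sires with per-offspring unique dams,
  mirroring stallion-centred pedigrees in horse breeding, where nearly
  every dam appears once;
* optional admixture: a fraction λ of one class draws each allele from
  either of two parent populations according to an ancestry mix —
  emulating open studbooks that admit sires from a neighbouring breed.

`simulate_liability_trait()` generates binary labels through the
threshold model's own generative direction (`l = Zu + e`), with marker
effects rescaled so the realized in-sample heritability is exactly the
requested value.

Everything is deterministic given `seed`.

## Numerical choices and degenerate inputs

* Missing genotypes surviving the ≥ 90 % call-rate filter are mean-imputed
  to `2·freq`; centered covariates then contribute exactly zero, and
  per-marker frequencies are unchanged by imputation. (How the original
  study handled residual missingness is not stated; this is the package's
  choice.)
* MAF filtering uses a strict `<` at the threshold (a marker at exactly
  0.05 is kept) and is computed on non-missing calls.
* Relationship matrices that fail Cholesky get a logged jitter of 1e-8
  (1e-6 in the heritability animal model, where G from fewer markers than
  samples is routinely semidefinite).
* Eigenvalues are clipped at zero for explained-variance accumulation;
  negative numerical eigenvalues are excluded from variance totals.
* Pairwise probabilities of exactly 0/1 (e.g. from a perfectly separated
  fit) are clipped into the open interval before coupling.
* Centering frequencies default to the whole provided sample; LOO folds
  recompute them on the training fold (leakage-free), clamped into
  (1e-6, 1-1e-6) when applied to held-out genotypes.
* Ties (argmax of class probabilities, OVO voting cycles, minor-allele
  choice in PLINK input) break deterministically to the lowest index /
  alphabetically first, with a warning where scientifically relevant.

## Problem sizes used in the validation suite

The test suite validates on simulations sized for a desk run: F_ST
recovery on 2 × 200 samples × 5,000 markers over F ∈ {0.01, 0.05, 0.1,
0.2}; heritability recovery at n = 400, m = 200 over three seeds;
leave-one-out classification at K = 3, n = 60, m = 500 (with a
permuted-label null); eigenvector-inclusion analysis at N = 100, m = 800,
F = 0.5; coupling inversion over 1,000 random simplex vectors with
K ∈ 2…6. Chain lengths follow the package defaults (30,000/15,000 for
single fits, 60,000/20,000 for pEV and heritability, 2,000/500 inside CV
folds) except where a shorter, explicitly passed spec suffices for the
quantity under test.

## Known limitations

* Binary contrasts assume independence of irrelevant alternatives; a
  multinomial probit with correlated liabilities is out of scope.
* pEV inclusion probabilities under saturated designs are not calibrated
  against label noise (see above).
* The simulator has no linkage disequilibrium, selection, or genotyping
  error; accuracy measured on it is an upper bound relative to real data
  with comparable divergence.
* Only the linear kernel is wired into the SVM adapter, and it yields
  discrete labels only (no Platt scaling).
* Sparse-pedigree inverse-A machinery (Henderson's rules) and single-step
  H matrices are not implemented; pedigrees are handled densely.
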
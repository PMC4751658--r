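# genoclass

Genomic prediction of **unordered categorical traits** — breed or
subpopulation assignment, coat colour, any K-class trait whose classes have
no meaningful order — from genome-wide SNP genotypes.

Unordered classes rule out ordinal threshold models. genoclass instead
decomposes the K-class problem into binary contrasts, fits each contrast
with a Bayesian **probit threshold model**

    Pr(y = 1 | eta) = Phi(eta - delta),   eta = W b + Z u,   l = eta + e,  e ~ N(0, I)

by data-augmentation Gibbs sampling (ridge/GBLUP, BayesA, or BayesC-pi
priors on the marker effects `u`), and reassembles the binary posterior
predictive probabilities into a K-simplex vector by either

* **one-vs-all normalization** — `p_k = Pr_k / sum_l Pr_l`, or
* **one-vs-one pairwise coupling** — solving the stationarity system
  `p = Qp` implied by `p_kk' = p_k / (p_k + p_k')`, or
* **one-vs-one voting** — the counting measure over pairwise winners
  (the route for label-only backends such as the bundled linear-SVM
  adapter).

Around this core the package provides:

* leave-one-out cross-validation with accuracy, Brier score and scaled
  Brier score (`sBS = 1 - BS/BS_uniform`), per class and total;
* VanRaden genomic (`G = MM'/Σ2p(1-p)`) and pedigree numerator (`A`)
  relationship matrices, eigendecompositions and Cholesky feature
  factorizations (regression over the pedigree instead of the markers);
* population-divergence statistics: pairwise Weir–Cockerham and global
  mixed-model F_ST, eigenvector-inclusion analysis (pEV / nEV) under a
  spike-slab probit, liability-scale heritability of subpopulation
  assignment (`h2 = sigma2_a / (sigma2_a + 1)`);
* multinomial breeding values: expected offspring class fractions
  `p_nk ∝ Phi(wbar'b_k + 0.5 (z_n - 2f)' u_k)` and deviations
  `g_n = p_n - p_0`;
* a Balding–Nichols synthetic-population simulator (divergence parameter
  F, optional admixture, half-sib families from shared sires) that makes
  every stage testable at desk scale;
* standard I/O: VCF, PLINK text, dosage TSV, labels/pedigree CSV, QC
  filtering (MAF < 0.05, call rate ≥ 90 %, mean imputation), and an
  opposing-fixation scan.

Results come back as tibbles with `tidy()`, `glance()` and `autoplot()`
methods; a command-line front-end (`exec/genoclass`) exposes the pipeline
as `simulate | qc | grm | fit | predict | cv | fst | pev | h2 | ebv`
subcommands.

## Worked example

```r
library(genoclass)

# three subpopulations, 20 individuals each, 500 unlinked SNPs, F = 0.15;
# half of pop3 is 50/50 admixed with pop1
sim <- simulate_population(K = 3, n_per_class = 20, m = 500, F = 0.15,
                           admixture = list(classes = c("pop1", "pop3"),
                                            lambda = 0.5, mix = 0.5),
                           seed = 42)
g <- qc_filter(sim$genotypes)          # MAF < 0.05 and call rate < 90% removed
length(g$markers)
#> [1] 459

fst_pairwise(g, sim$labels, "pop1", "pop2")
#> <fst_result> scope=pairwise(pop1,pop2), convention=wc
#>   markers: 459, mean=0.1186 (sd 0.1519), multilocus estimate=0.1442

cv <- loo_cv(g, sim$labels, scheme = "ova", backend = "ridge", seed = 1)
cv
#> <cv_result> leave-one-out, scheme=ova, backend=ridge
#>   class  n accuracy  brier   sbs
#> 1  pop1 20        1 0.0918 0.862
#> 2  pop2 20        1 0.0516 0.923
#> 3  pop3 20        1 0.1565 0.765
#> 4 Total 60        1 0.1000 0.850

pev_analysis(g, dplyr::filter(sim$labels, class %in% c("pop1", "pop2")),
             spec = threshold_model_spec("bayes_c_pi", n_iter = 20000,
                                         burn_in = 5000, seed = 2))
#> <pev_result> classes pop1 vs pop2 (N=40)
#>   pEV=0.0942  nEV=3.6728  top inclusion=1.000
```

Reading the output: every individual is classified into its simulated
subpopulation (accuracy 1.00); the admixed pop3 shows the weakest
probabilistic calibration (sBS 0.765 against 0.923 for the clean pop2);
the two-population multilocus F_ST estimate (0.144) recovers the
between-population divergence of two populations each drifted at F = 0.15
from a common ancestor; and a single eigenvector of the genomic
relationship matrix suffices to separate pop1 from pop2 (top inclusion
probability 1.0, nEV ≈ 3.7).

The same pipeline runs from the shell:

```sh
exec/genoclass simulate --K 3 --n 20 --m 500 --F 0.15 --seed 42 --out sim/
exec/genoclass cv --genotypes sim/genotypes.tsv --labels sim/labels.csv \
                  --scheme ova --classifier ridge --seed 1 --out cv/
```

## Method notes

The methods vignette
(`vignettes/multinomial-genomic-classification.Rmd`) documents the model,
its identification constraints, the prior-scale heuristic, the block
Gibbs update that the ridge sampler requires, estimator conventions for
F_ST, the eigenvector-scaling choice in pEV, and what the unlinked-marker
simulator can and cannot certify about real data.
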
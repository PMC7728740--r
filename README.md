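# gpdeep

Genomic prediction and marker-effect recovery for plant breeding panels, in
one package: the Bayesian alphabet of whole-genome regressions, GBLUP and
Gaussian-kernel RKHS, Bayesian-regularized feed-forward networks, LSTM
regression on SNP dosages, REML heritability, a repeated cross-validation
harness with Tukey–Kramer model comparison, and the iterative back-solving
algorithm that turns any model's predicted genetic values into per-SNP
effects for QTL discovery.

## The problem

Breeding programs predict the genetic merit of unphenotyped selection
candidates from genome-wide SNP genotypes. Given a panel of n individuals
with pre-corrected phenotypes y and a dosage matrix of p biallelic SNPs
coded 0/1/2, every model here estimates the map from marker genotypes to
genetic value, and is scored by *predictive ability* (PA): the Pearson
correlation between observed and predicted phenotypes in held-out
validation sets over repeated 90/10 splits.

All linear models share

```
y_i = mu + sum_j A_ij a_j (+ D_ij d_j) + e_i,   e ~ N(0, I sigma2_e)
```

with the additive design `A in {0,1,2}` and the dominance design
`D in {0,1,0}`, and differ in the prior on the marker effects `a_j`:

| model    | prior on a_j                                             |
|----------|----------------------------------------------------------|
| BRR      | Normal, one common variance (scaled-inv-chi^2 prior)     |
| BL       | double exponential (Park–Casella hierarchy)              |
| Bayes A  | Normal with marker-specific scaled-inv-chi^2 variances   |
| Bayes B  | point mass at 0 w.p. pi + Bayes-A slab (pi fixed)        |
| Bayes Cpi| point mass + common-variance slab, pi ~ Beta sampled     |

All five are fitted by single-site Gibbs sampling with conjugate full
conditionals (compiled core). GBLUP solves the equivalent mixed model on
the VanRaden relationship matrix `A = WW'/(2*sum p_i q_i)`; RKHS replaces
it with the Gaussian kernel `K = exp(-h * d2)` on pairwise squared
distances normalized to [0, 1]. Variance components come from AI-REML
(EM warm-up, average-information refinement), giving the heritability
ratios `h2 = s2a/(s2a+s2e)`, `H2 = (s2a+s2d)/(s2a+s2d+s2e)`, and the
additive/dominance ratios `ha2`, `hd2` with delta-method standard errors.

The machine-learning side implements the ten `brnn1`–`brnn10` feed-forward
architectures (purelin/logsig/tansig, 1–3 layers) trained by
Levenberg–Marquardt with MacKay evidence updates of the regularization
pair, and the six `lstm1`–`lstm6` LSTM regressions crossing the state
activation (Tanh/ReLU) with the mini-batch fraction (10/50/100%).

Finally, per-SNP effects are back-solved from any model's genetic values
`a_hat` by the three-iteration weighted algorithm

```
u_t = D_t Z' [Z D_t Z']^{-1} a_hat,   D_{t+1} propto diag(u_i^2 * 2 p_i q_i),
tr(D_{t+1}) = p
```

which sharpens the contrast between large- and small-effect markers so
markers above a trait-specific threshold can be called as QTL.

## Worked example

```r
library(gpdeep)
G   <- simulate_genotypes(n = 300, p = 1000, seed = 7)
sim <- simulate_trait(G, n_qtl = 10, h2a = 0.5, seed = 8)

vc <- fit_reml(sim$phenotypes, additive_relationship(G))
heritability_ratios(vc, "narrow")
#>   ratio  estimate        se
#> 1    h2 0.7282396 0.1213745

models <- list(GBLUP  = kernel_model("GBLUP"),
               BayesB = gibbs_config("BayesB", n_iter = 2000,
                                     burn_in = 500, thin = 5))
cv <- run_cv(models, G, sim$phenotypes, n_cycles = 5, seed = 9)
cv_summary(cv)[, c("model", "mean_pa", "sd_pa", "letters")]
#>    model   mean_pa     sd_pa letters
#> 1 BayesB 0.3844464 0.1487079       a
#> 2  GBLUP 0.3101149 0.1257547       a

fit  <- fit_kernel_blup(sim$phenotypes, additive_relationship(G), vc = vc)
backsolve_effects(G, fit$values)
#> EffectTrajectory: 1000 markers, 3 iterations
#>   iter 1: max|u| = 0.1604, median|u| = 0.01364
#>   iter 2: max|u| = 0.2573, median|u| = 0.004611
#>   iter 3: max|u| = 0.2684, median|u| = 0.000974
```

The REML h2 estimate (0.73 ± 0.12) brackets the simulated value 0.5 within
two standard errors at this panel size. Both models reach a mean PA of
0.31–0.38 over five 90/10 cycles and share the Tukey–Kramer letter "a"
(no significant difference). The back-solve trajectory shows the
sharpening that motivates its use for QTL discovery: the largest absolute
effect grows while the median collapses, so the max/median contrast rises
from ~12 to ~276 across the three iterations.

## Analysis workflow

The `analysis/` scripts rebuild the study end to end on synthetic data and
write their tables under `results/`:

1. `01_simulate.R` — panel + signal/dominance/null traits with known truth
2. `02_heritability.R` — marker QC, REML components, heritability ratios
3. `03_cross_validation.R` — shared-split CV across the full model panel
4. `04_model_comparison.R` — Tukey–Kramer compact-letter summary
5. `05_snp_effects.R` — back-solved effect trajectory and QTL calls

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package — simulation, QC, REML, shared-split cross-validation
over GBLUP/RKHS/BRR/brnn1/lstm5, and the iterative back-solve with QTL
calls — seeded entirely from `--seed`, and writes its JSON report to
`--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
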
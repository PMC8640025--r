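# ecar

Correlation-adjusted variable-importance scores for high-dimensional linear
regression, with data-driven tuning of the adjustment strength and
false-discovery-rate feature selection.

## The problem

Molecular studies routinely regress a continuous trait (expression of a
phenotype, lung function, spike length) on thousands of correlated genomic
features measured on a few hundred samples. Marginal screening (ranking by
|Pearson correlation|) is robust in heavy noise but credits "hitchhiker"
features that are merely correlated with the causal ones; multiple-regression
coefficients credit only direct contributions but are hopeless to estimate
when p >> n. `ecar` implements the family of scores

    omega = R^(-alpha) * R_XY ,        alpha in [0, 1]

where `R_XY` is the vector of marginal correlations of the (standardized)
features with the outcome and `R` is the feature correlation matrix,
estimated with Schafer-Strimmer shrinkage towards the identity so its
fractional power `R^(-alpha)` (computed from the spectral decomposition
`R = Q L Q'` as `Q L^(-alpha) Q'`) always exists. The exponent interpolates
between the two extremes:

| alpha | omega equals |
|-------|--------------|
| 0     | marginal Pearson correlations (SIS screening) |
| 0.5   | CAR scores (Zuber & Strimmer) |
| 1     | semi-partial correlations (standardized regression coefficients) |

The package's core contribution is choosing `alpha` per dataset: holding the
observed design fixed, it simulates responses `y = X b + e` at the estimated
signal strength R² (refitted cross-validation) and sparsity s (GCV-tuned
lasso support), with noise calibrated so the population R² is exact
(`sigma² = (1-R²) b'X'Xb / (n R²)`); for each of 100 simulated replicates it
records the grid alpha (0, 0.05, ..., 1) maximizing the precision-recall AUC
of the |score| ranking against the simulated truth, and reports the median.
Low R² pushes alpha towards 0 (marginal behaviour), high R² towards 1.

Selection at a target FDR uses an empirical-null fit: a truncated-ML
half-normal null on |scores| plus a Grenander estimate of the mixture
density, giving local fdr and tail-area Fdr per feature.

## Worked example

```r
library(ecar)
set.seed(1)

# benchmark design: 200 samples, 600 features in two compound-symmetry
# blocks (within-block correlation 0.25); 30 influential features in the
# first block, noise calibrated so the population R^2 is 0.6
X    <- make_block_design(block_design_spec(n = 200, p = 600, seed = 1))
resp <- make_response(X, s = 30, r_squared = 0.6,
                      placement = "first_block", seed = 2)

est <- estimate_alpha(X, r_squared = 0.6, s = 30, B = 100, seed = 3)
est
#> alpha estimate: median 0.450 (sd 0.120) over 100 replicates [R2 = 0.6, s = 30]

scores <- ecar_scores(X, resp$y, alpha = est$median)
print(scores, n = 5)
#> ECAR score table: 600 features, alpha = 0.45
#>  feature_id     score abs_score rank alpha
#>        f130 0.1859197 0.1859197    1  0.45
#>        f298 0.1330954 0.1330954    2  0.45
#>         f50 0.1313834 0.1313834    3  0.45
#>          f3 0.1308561 0.1308561    4  0.45
#>         f45 0.1284156 0.1284156    5  0.45

sel <- select_features(scores, fdr_level = 0.05)
sum(sel$selected)                      #> 1   (the one selected feature is a true positive)
pr_auc(scores, resp$truth)             #> 0.297
```

The estimated exponent 0.45 sits between marginal screening and CAR, as
expected at moderate R². At this noise level the 5%-FDR cut is conservative
(one confident discovery); the full ranking still concentrates true
positives near the top (PR-AUC 0.30 against a base rate of 30/600 = 0.05).

## Command-line interface

The installed script `exec/ecar` (or `ecar::ecar_main()`) exposes the
pipeline:

```sh
ecar score          --data X.tsv --outcome y.tsv [--alpha 0.45] --out scores.tsv
ecar estimate-alpha --data X.tsv --outcome y.tsv [--r2 0.6 --s 30] --out alpha.json
ecar select         --scores scores.tsv --fdr 0.05 --out selection.tsv
ecar simulate       --preset block-first --r2 0.95 --reps 100 --seed 1 --outdir sims/
ecar benchmark      --r2 0.8 --reps 100 --methods ecar,car,sis,ridge,lasso,stability --out results.json
```

Outputs are TSV with a `#` metadata header (version, seed, parameters) or
JSON; every run with `--seed` is bit-reproducible.

## Package layout

- `R/standardize.R`, `R/shrinkage.R`, `R/scores.R` — feature matrix,
  shrinkage correlation model, spectral matrix powers, score computation
  (dense reference path and an SVD fast path that agree to 1e-8).
- `R/estimate.R`, `R/alpha.R` — R²/s estimation and the alpha-tuning
  simulation.
- `R/fdr.R` — empirical-null FDR selection.
- `R/simdata.R` — block compound-symmetry designs, calibrated responses,
  semi-synthetic expression loader.
- `R/benchmark.R` — SIS/ridge/lasso/stability-selection competitors,
  PR-AUC, true-positive paths, train/test MSE protocol.
- `R/cli.R`, `R/io.R` — command-line interface and text I/O.
- `vignettes/ecar-methods.Rmd` — modelling assumptions, tuning parameters,
  numerical choices, and what the synthetic designs do and do not emulate.
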
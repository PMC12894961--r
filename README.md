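# hsrtrait

Leaf hyperspectral reflectance (HSR) — the fraction of light a leaf reflects,
measured on a near-continuous 400–2400 nm grid — carries signatures of leaf
structure, biochemistry and physiology. Regressing measured traits (specific
leaf area, nitrogen percentage, photosynthetic capacity, chlorophyll
fluorescence parameters, ...) on these spectra promises cheap, high-throughput
phenotyping for breeding programmes. The catch is validation: a model that
looks excellent under random cross-validation may collapse when asked to
predict a genotype it has never seen, or a growing season with different
environmental conditions.

`hsrtrait` is an R package for building and stress-testing such models. It
provides:

- **Models.** Univariate partial least squares regression, implemented from
  scratch with the NIPALS algorithm (sequential extraction of mutually
  orthogonal latent components maximising covariance with the response; one
  fit serves every component count `k` up to its maximum), and linear-kernel
  ε-insensitive support vector regression (solver delegated to libsvm via
  `e1071`, standardisation and original-scale coefficients handled here).
- **Calibration.** Three strategies for the PLSR number-of-components (NoC)
  hyperparameter: repeated k-fold cross-validation with a modal consensus
  across repetitions (default 20 × 5-fold), a single CV iteration, and the
  PRESS statistic accumulated over random train/test sub-samples (default
  100 × 80/20). SVR's cost `C` is tuned by CV MSE over a log-spaced grid.
  All ties break toward the smaller hyperparameter.
- **Validation scenarios.** A nested cross-validation engine whose outer
  fold plans cover random splits (generalizability), genotype-exclusive
  splits, whole-season holdout, and the strictest case — unseen genotypes in
  an unseen season. Inner-loop hyperparameter selection sees only the
  calibration rows and honours genotype exclusivity; a built-in audit
  hard-errors on any leakage. Metrics: per-fold R² and RMSE% for
  within-distribution scenarios, squared Pearson correlation (trend only)
  for season transfer, summarised as median and IQR across folds.
- **Preprocessing.** Plot/genotype replicate averaging, wavelength
  sub-sampling and windowing (e.g. 1500–2400 nm for nitrogen traits), and
  per-season trait centring/scaling for combining seasons whose trait levels
  shift.
- **Descriptive season comparison.** Trait coefficients of variation,
  between-season Spearman correlation of genotype means, cross-season
  correlation of genotype-mean spectra by wavelength region, and Mantel
  permutation tests on the genotype-covariance structure of the spectra.
- **A synthetic data generator.** Multi-season spectra and traits driven by
  a low-rank latent structure with genotype, season, plot,
  genotype-by-environment (G×E) and residual variance components, so every
  stage of the pipeline is testable without field data. The G×E deviation of
  a trait is drawn independently of the spectra's — the decoupling that
  actually limits cross-season transfer.

## Worked example

```r
library(hsrtrait)

cfg <- synthetic_config(n_genotypes = 40, n_seasons = 3,
                        plots_per_genotype = 2, reps_per_plot = 3,
                        wavelengths = seq(400, 2400, by = 10), n_latent = 5)
d <- generate_dataset(cfg, seed = 1)
d$spectra
#> <spectral_dataset> 720 samples x 201 wavelengths (400-2400 nm)
#>   genotypes: 40 | seasons: S1, S2, S3

res <- run_nested_cv(d$spectra, d$traits, "sla",
                     model = "plsr", aggregation = "genotype",
                     scenario = "unseen_genotype", k_folds = 5, reps = 5,
                     noc_grid = 1:12, seed = 1)
res
#> <evaluation_result> sla | plsr | unseen_genotype | aggregation = genotype
#>   25 validation folds (5 repetition(s) x 5 fold(s))
#>   r2: median 0.487 (IQR 0.198)
```

Each of the 25 validation folds held two unseen genotypes; the median R² of
0.487 says about half of the genotype-mean trait variance is recovered from
spectra alone for genotypes the model never saw. Season transfer is assessed
on the trend only:

```r
run_nested_cv(d$spectra, d$traits, "sla",
              scenario = "unseen_season", test_season = "S3",
              noc_grid = 1:12, seed = 1)
#> <evaluation_result> sla | plsr | unseen_season | aggregation = raw
#>   1 validation folds (1 repetition(s) x 1 fold(s))
#>   sq_pearson: median 0.549 (IQR 0.000)

season_summary(d$spectra, d$traits, n_perm = 999, seed = 1)$mantel
#>   seasonA seasonB  mantel_r p_value
#> 1      S1      S2 0.6924968   0.001
#> 2      S1      S3 0.6567812   0.001
#> 3      S2      S3 0.8214985   0.001
```

The Mantel statistics compare the genotype-covariance structure of the
spectra between seasons: high but clearly below 1, i.e. the seasons share
most, not all, of their covariance structure — the regime in which
cross-season transfer degrades.

`run_experiment()` orchestrates several traits × scenarios from one config
list and writes tidy per-fold CSVs plus JSON summaries;
`summarize_experiment()` turns the results into a report table with optional
paired Wilcoxon comparisons between scenarios.

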
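---
title: "Predicting leaf traits from hyperspectral reflectance: models, calibration and transfer scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting leaf traits from hyperspectral reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsrtrait)
```

## The problem

A leaf's reflectance spectrum over 400–2400 nm integrates its pigment
content, water status, internal structure and biochemistry. Regression models
mapping spectra to measured traits make spectroscopy a high-throughput proxy
for slow trait measurements. The scientific question this package is built
around is not *whether* such models can be fitted — they almost always can —
but *where they keep working*: on new random samples from the same
distribution, on genotypes absent from the calibration set, on an entirely
new growing season, or on both at once. These four regimes differ in what
information the model may exploit, and honest evaluation requires fold plans
that enforce the corresponding exclusions, inner loops that respect them too,
and metrics suited to each regime.

## Models

**PLSR.** Spectra are wide (hundreds to thousands of collinear wavelengths,
far fewer samples), which rules out ordinary least squares. Partial least
squares regression extracts components sequentially: each is the direction in
predictor space maximising covariance with the current response residual,
after which both predictors and response are deflated. `fit_plsr()`
implements the NIPALS variant (the classical deflation algorithm; SIMPLS
would be an equally valid choice, and the package's oracle tests — exact
agreement with minimum-norm least squares at the full component count — hold
for either). Design choices:

- Predictors are mean-centred but *not* scaled to unit variance by default:
  reflectance columns share units, and variance differences across
  wavelengths are informative. `scale = TRUE` is available.
- One fit at `max_noc` serves the whole component grid: the stored weight and
  loading structure yields the coefficient vector and intercept for every
  `k <= max_noc`, so calibration over a grid of 40 candidates costs one fit
  per fold, not forty.
- Component extraction stops early when the deflated predictor matrix falls
  below `1e-12` of its initial squared Frobenius norm (or a weight/score norm
  vanishes). Grid values beyond the effective maximum reuse the converged
  model rather than erroring, so a 1–40 grid is safe on small folds.
- A constant response returns a valid model (zero coefficients, intercept
  `mean(y)`) rather than an error, since degenerate folds occur in permuted
  or null-simulated data.

**Linear SVR.** To compare model families without confounding by
nonlinearity, the alternative model is support vector regression with a
linear kernel only. The ε-insensitive quadratic programme is delegated to
libsvm (`e1071::svm`); `fit_linear_svr()` standardises predictors and
response internally and reports the affine function on the original scales.
ε is fixed at 0.1 on the standardised response, so `C` is the single tuned
hyperparameter. When every residual fits inside the tube the flat function is
optimal and is returned explicitly (libsvm reports an empty model there).

## Calibration: choosing the number of components

The NoC hyperparameter governs the bias–variance trade-off of PLSR, and
different communities select it differently. The package implements three
selectors behind one result type:

- `select_noc_repeated_cv()` — the repeated double-CV tradition: 20
  repetitions of 5-fold CV by default; each repetition selects its own MSE
  minimiser, and the consensus is the mode across repetitions. The full
  per-repetition error curves are retained so the qualitative shape of the
  NoC response (monotone rise, plateau, overfitting decline) can be plotted
  past the optimum.
- `select_noc_single_cv()` — one CV iteration (3-fold by default; the fold
  count of a "single CV iteration" is genuinely open, and 3 mirrors the
  repeated inner scheme). This is the fast default for nested-CV inner loops.
- `select_noc_press()` — the sub-sampling tradition: 100 random 80/20
  train/test splits, squared prediction errors accumulated per candidate,
  minimum total PRESS wins. The global minimum is used rather than a
  one-standard-error rule.

All ties break toward the smaller hyperparameter (parsimony); this also
preserves the tendency of PRESS to favour slightly smaller NoC. SVR's cost is
selected by CV MSE over a 9-point log-spaced grid spanning 1e-3 to 1e3, a
range wide enough that the optimum is interior on clean data.

Randomness is controlled by one master seed; every repetition, sub-sample and
fold plan derives a child seed by counter (`child_seed()`), so results are
bit-reproducible and independent of execution order.

## Scenarios, leakage and metrics

`build_fold_plan()` constructs the outer loops:

- `random`: stratification-free k-fold CV per repetition (default 20 × 5,
  i.e. 100 validation folds).
- `unseen_genotype`: genotypes are partitioned into folds (sizes differing by
  at most one) and every row follows its genotype.
- `unseen_season`: calibration is the whole of the training season(s),
  validation the held-out season — one fold.
- `unseen_genotype_unseen_season`: the target season's genotypes are split
  into k validation folds; calibration is the other seasons *minus* the
  validation genotypes. Passing a single `train_seasons` value gives the
  single-training-season variant. (Published descriptions of this design
  differ between a single- and a multi-season training set; the multi-season
  version is the default here and the other remains available, with no claim
  about which is canonical.)

`audit_fold_plan()` re-derives the exclusivity guarantees from the indices
themselves — disjointness, partition of the eligible rows, genotype
exclusivity, no test-season rows in calibration — and hard-errors otherwise.
`run_nested_cv()` always audits before fitting, and inner-loop selectors
receive the genotype grouping whenever the outer scenario enforces it, so the
inner folds cannot leak genotypes either. The season-holdout inner loop uses
random splits within the multi-season calibration set.

Metrics are computed per validation fold and summarised by median and IQR
across folds — never pooled, since pooling hides fold-to-fold variability.
Within-distribution scenarios use the coefficient of determination
(`1 - SS_res/SS_tot`, about the fold's observed mean; negative values are
meaningful) and RMSE%. RMSE% is defined as `100 * RMSE / mean(obs)` — the
common chemometrics normalisation; range-normalisation is available via
`normalize = "range"`. Season transfer is scored by squared Pearson
correlation, which is invariant to affine miscalibration and therefore
assesses the *trend* of the predictions; when trait magnitudes shift between
seasons, agreement-based metrics conflate the shift with loss of signal.

Trait preprocessing follows the registry attached to the trait table:
nitrogen-type traits restrict spectra to 1500–2400 nm; traits whose level
shifts between seasons can be centred and scaled within each season before
seasons are combined for training (`center_scale_by_season()`). Missing trait
cells are dropped pairwise per trait at fitting time; spectra rows are never
dropped globally. Aggregation to plot or genotype level averages reflectance
wavelength-wise with the plain arithmetic mean and trait values with a
missing-aware mean; collapsed hierarchy levels carry the sentinel `"*"`.

## The synthetic generator

`generate_dataset()` emulates a multi-season field trial: by default 320
genotypes × 3 seasons × 2 plots × 3 replicates on a 1 nm, 400–2400 nm grid —
the scale of a large phenotyping experiment. Each latent factor's per-sample
score decomposes into Gaussian genotype, season, genotype-by-season (G×E),
plot and residual effects; spectra are a smooth leaf-like baseline plus the
scores mapped through Gaussian-bump basis functions plus smooth measurement
noise, clipped to [0, 1] (with a warning if clipping exceeds 5% of values);
traits are linear in latent scores plus noise, with optional per-season mean
shifts and injectable missingness.

Default variance components (latent-score scale): genotype 1.0 — the
dominant, heritable signal a phenotyping panel is designed around; season 0.5
— a strong but secondary environmental main effect; G×E 0.3 — present but
smaller than the main effects; plot 0.05 — small spatial effects; residual
0.2. One season raises the 750–1500 nm near-infrared plateau by 0.05,
mimicking a season with anomalous reflectance so transfer-failure modes are
reproducible.

One modelling decision deserves emphasis. If the trait were an exact linear
function of the *same* latent scores that generate the spectra, G×E variance
would be shared signal: a model trained in one season would recover it from
the spectra of another season, and raising G×E would make transfer *easier*.
What limits transfer in reality is that a trait's environment-specific
response and its optical signature decouple. The generator therefore draws
the genotype-by-season deviation of the trait scores independently of the
spectral scores, while sharing the genotype, season, plot and residual
components. With `sigma2_GxE = 0` the two coincide. Under this design,
increasing `sigma2_GxE` strictly decreases unseen-season transfer (verified
in the test suite over three levels × 10 seeds), while leaving within-season
structure intact.

What the generator does *not* emulate: radiative-transfer leaf optics (the
basis functions are statistical, not PROSPECT-like), spatial field structure
(alpha-lattice neighbour effects), instrument artefacts (detector splices,
water-band noise), non-Gaussian trait distributions, and
wavelength-dependent error correlation beyond the smooth noise basis.
Passing tests therefore demonstrate that the *pipeline logic* (fold
exclusivity, calibration behaviour, metric properties, qualitative orderings)
is correct, not that any particular field accuracy will be attained.

## Numerical choices and degenerate inputs

- NIPALS stopping: weight/score norms below `1e-12`, or deflated X below
  `1e-12` of its initial squared norm; score orthogonality is tested at
  relative `1e-8`.
- NoC grids are truncated to `min(n_train - 1, p)` per fold; an entirely
  infeasible grid errors with the feasible maximum.
- Argmin and mode ties always resolve to the smallest candidate.
- `r_squared()` errors on constant observations; `squared_pearson()` on
  either vector constant; `rmse_percent()` on a zero normaliser. Inside the
  engine these degenerate folds yield `NA` and are excluded from summaries.
- The Mantel permutation p-value uses the `(count + 1)/(n_perm + 1)`
  estimator (one-sided upper, simultaneous row/column permutation);
  `exact = TRUE` enumerates all `n!` permutations (n ≤ 8) and returns the
  enumeration proportion including the identity.
- "Correlation of genotype-mean spectra between seasons" is read as
  per-genotype correlation across wavelengths, averaged over genotypes; the
  per-wavelength-across-genotypes reading is available via `method =
  "per_wavelength"`.
- CSV writers emit 17 significant digits so written datasets read back
  bit-identically.

## Problem sizes used by the tests and the acceptance script

Desk-scale runs keep the suite fast while preserving the phenomena: NoC
recovery uses noiseless 3-factor data at n = 120, p = 401; strategy
agreement uses 40 genotypes × 1 season (240 rows, 201 wavelengths) under the
default noise; scenario ordering and G×E monotonicity use 30–60 genotypes ×
3 seasons over 10 seeds; the aggregation contrast uses 80 genotypes (an
aggregated panel much smaller than that leaves too few calibration rows for
a stable inner loop, which is itself a finding worth knowing when planning a
trial). The full 320-genotype, 2001-wavelength default remains the
generator's reference condition.

## Known limitations

- PLSR is univariate; multi-response PLSR is out of scope.
- Only the linear SVR kernel is provided, by design.
- Per-season centring/scaling uses each season's own statistics; in a true
  deployment the target season's statistics may be unavailable, and squared
  Pearson (used for transfer) is the only shipped metric invariant to that
  choice.
- The Wilcoxon scenario comparison is a reporting annotation (paired over
  repetition means), not a calibrated hypothesis test across dependent folds.
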
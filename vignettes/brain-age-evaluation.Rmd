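---
title: "Evaluating brain-age models: metrics, bias correction and cohort effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating brain-age models: metrics, bias correction and cohort effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainagekit)
```

## The problem

A brain-age model regresses chronological age on neuroimaging features and is
judged by Pearson's *r*, *R*², RMSE and MAE between its out-of-sample
predictions and true age. All four metrics are functions not only of the
model but of the evaluation cohort: a correlation computed over a restricted
age range is attenuated; error metrics scale with the age spread of the test
set and with the mean-age difference between training and test sets; and the
standard age-bias correction can make arbitrarily poor models look accurate.
`brainagekit` implements each ingredient of this argument as a testable
operation, so the phenomena can be reproduced end to end on synthetic data.

## The model behind the synthetic cohorts

`generate_cohort()` draws ages from either a truncated normal (mean 64.15,
SD 7.54, range 45–82 years — the shape of a large mid-to-late-life biobank
cohort) or a uniform distribution on 18–87 years (a wide lifespan cohort).
Each of *p* features (default 180, the scale of an atlas-based morphometry
set) is a linear function of age plus i.i.d. Gaussian noise:

  *f\_{ij}* = *a\_j* · ageᵢ + siteᵢⱼ + εᵢⱼ,  εᵢⱼ ~ N(0, σ\_noise²).

Slopes have fixed magnitude `slope_scale` with alternating signs, reflecting
that brain measures both shrink and grow with age. With equal per-feature
signal-to-noise, the optimal linear read-out averages the per-feature age
estimates, leaving residual noise of SD σ\_noise/(|a|√p) on the age scale.
`target_model_r` inverts this relation: given the cohort's realised age SD
σ\_age, the noise is set to

  σ\_noise = |a| √p σ\_age √(1/r² − 1),

so a well-fit linear model approaches the requested out-of-sample
correlation r. The default target of 0.73 matches the headline accuracy of
large-cohort morphometry models, making the synthetic experiments
numerically comparable to published full-sample results.

What the generator deliberately does **not** emulate: the correlation
structure among real morphometric features (here noise is independent across
features), nonlinear lifespan trajectories, heteroscedasticity with age, and
pathology subgroups. Passing tests therefore demonstrate the *statistical*
mechanisms — range restriction, mean-shift effects, correction-induced
inflation — which hold for any least-squares pipeline, but say nothing about
how large these effects are in any particular imaging dataset.

## Preprocessing conventions

* `robust_scale()` maps each feature to (x − median)/(q75 − q25) with
  linear-interpolation (type 7) quantiles, the common robust-scaler default.
  Constant features are scaled by 1 with a warning. Parameters are fitted on
  training data and applied unchanged to test data everywhere in the
  package.
* `residualise_site()` removes additive per-site offsets by OLS on site
  indicators and adds back the grand mean, preserving the feature scale and
  units. Retaining the grand mean (rather than leaving zero-centred
  residuals) is a design choice made for interpretability; it does not
  change any downstream fit.
* `exclude_outliers()` is single-pass: mean and SD are computed once on the
  full input, and values ≥ k SD (default 3) from the mean are dropped. No
  iteration, because re-computing moments after removals makes the rule
  order-dependent and harder to report.

## Prediction harness

`crossval_predict()` assigns folds by a seeded random permutation followed
by contiguous chunking (fold sizes differ by at most one) and predicts each
fold from a model trained on the others, with robust scaling refitted inside
every training fold. Per-fold scaling is slightly more conservative than
scaling once globally; it guarantees the train→test contract even during CV.

The regressor is pluggable: anything with `fit_regressor()` /
`predict_regressor()` methods. The default is closed-form L2-regularised
linear least squares (`ridge_regressor()`, unpenalised intercept, λ = 1 on
robust-scaled features). A linear baseline is deliberate: the phenomena
under study are consequences of least-squares fitting itself and are
insensitive to the choice of learning algorithm, while a deterministic
closed-form fit keeps every experiment exactly reproducible and fast.
Gradient-boosted trees (`xgboost_regressor()`) are available for
cross-checks. Hyperparameter search is intentionally out of scope — it is
orthogonal to how the metrics behave.

## The age-bias correction family

With predictions ŷ and ages Ω, the bias fit is OLS of ŷ on Ω
(`route = "prediction"`, slope α, intercept β) or equivalently of the delta
ŷ − Ω on Ω (`route = "delta"`, slope α − 1, same intercept). The additive
correction is

  corrected ŷ = ŷ + (Ω − (αΩ + β)).

Applied with an in-sample fit, OLS residual orthogonality makes
corr(corrected delta, Ω) exactly 0 — and for a constant predictor the
corrected predictions equal Ω exactly, the algebraic kernel of the
correction's ability to make poor models look perfect. The quadratic
variant adds a γ(Ω − Ω̄)² term; age is centred before squaring to reduce
collinearity with the linear term, and the centring constant is stored in
the fit so coefficients remain interpretable.

The slope-division correction, corrected ŷ = (ŷ − β)/α, preserves prediction
ranks for α > 0 and inflates delta variance by 1/α². Both in-sample and
train-derived fit sources are supported and labelled, because comparing them
is itself one of the experiments.

## Metrics and uncertainties

All SDs and RMSE use the divide-by-N (population) convention, matching the
defining equations. *R*² is computed about the *test-set* true-age mean and
may be negative. When predictions have zero variance, *r* is reported as
`NA` with an explicit flag — never silently 0 — since an undefined
correlation is diagnostic of a collapsed model.

Alternative error metrics: RSE = 1 − *R*² identically, RAE, median absolute
error, and a weighted MAE whose weights are inversely proportional to
2-year age-bin counts. No single weighted-MAE convention exists; the binned
inverse-frequency definition was chosen because it flattens the age
distribution's influence, and the definition string is embedded in the
output so consumers know exactly what was computed.

Metric uncertainties are bootstrap SDs over 200 pair resamples (the
reporting convention); percentile intervals can be derived from the same
machinery but are not the headline. Per-individual uncertainty
(`individual_uncertainty()`) bootstraps the *training set*: N models
(default 500) fitted to resampled training sets yield a distribution of
predictions per test subject, summarised as μ, σ and the proportion of delta
draws above a clinical threshold. Note that σ captures training-resampling
variability only; covering a subject's true age requires adding the residual
prediction error, which is why the test suite checks coverage against
√(σ² + residual variance) rather than σ alone.

## Experiment designs

Six designs reproduce the cohort-effect phenomena; each cell records, next
to the uncorrected and corrected metrics, the two diagnostics that explain
them — SD of predictions and train–test mean-age difference:

* `run_full_cv()`: full-range CV in two cohorts with identical per-feature
  signal; the wide-range cohort shows larger *r* **and** larger RMSE.
* `run_vary_test_range()`: fixed full-range training set, test ranges
  narrowing 45–82 → 65–82. *r* falls monotonically; RMSE/MAE first fall
  (smaller range) then rise (growing mean-age difference); *R*² turns
  negative in the narrowest range.
* `run_vary_train_range()`: training ranges vary against a fixed 65–82 test
  set. *r* is nearly constant (set by the test range) while *R*² swings by
  an order of magnitude more.
* `run_equal_ranges()`: CV within equal-range subsets, optionally crossed
  with sample fractions 2.5–100%; every metric falls with a narrower range
  and improves with size.
* `run_shuffle()`: ages of 0/10/25/50/75% of subjects permuted; prediction
  SD and *r* fall with the fraction while corrected *r* rises — the
  correction gain is largest for the worst models.
* `run_split_half_correction()`: bias coefficients fitted in one half's
  predictions and applied to the other; at large n the train-derived and
  in-sample corrections agree to well under 0.01 in corrected *r*.

"Sample size held constant" is implemented as: count the subjects available
in the narrowest range (after the 50/50 split where one applies), then
subsample every other cell to that count with the cell's derived seed,
without age stratification. The lower-limit-constant cross-check is exposed
through `default_age_ranges(fix = "lower")` rather than as a separate
design.

## Numerical and design choices

* All randomness flows through explicit integer seeds; derived cell seeds
  use a fixed affine map modulo a 31-bit prime, so no global RNG state
  leaks between operations.
* Truncated-normal ages use rejection sampling (the truncation is mild, so
  acceptance is high and the draw remains exactly seeded).
* The shuffle operation permutes ages *within* the selected subset only,
  preserving the age multiset and leaving unselected subjects' labels
  untouched. Reassignment with replacement would change the marginal age
  distribution and was rejected.
* Degenerate inputs fail loudly with classed errors (invalid argument,
  degenerate input, empty subset, division-degenerate) rather than
  returning silent defaults.
* Experiment defaults run at 20,000 synthetic subjects with 180 features —
  the scale at which the seed-averaged orderings are stable and a full
  design completes in minutes on a single core with the linear baseline.
  Unit tests use smaller cohorts (hundreds to a few thousand subjects)
  chosen so each property is still decisive.

## Known limitations

* The generator's independence of feature noise makes prediction easier at
  a given per-feature signal-to-noise than in real morphometry, where
  correlated features carry redundant information; the `target_model_r`
  calibration absorbs this for the aggregate correlation but not for
  feature-level quantities.
* Site effects are additive constants; no multiplicative or
  variance-heterogeneity site models, and no empirical-Bayes harmonisation.
* Only linear (and centred-quadratic) bias corrections are implemented;
  covariate-adjusted delta models are out of scope.
* The weighted-MAE definition is a package convention, labelled as such in
  its output.
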
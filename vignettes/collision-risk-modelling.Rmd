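---
title: "Collision-risk modelling from gaze entropy and pupillometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision-risk modelling from gaze entropy and pupillometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gazerisk` estimates the probability that a driver fails a critical
takeover from SAE Level 2 automation — a collision — from three trial-level
physiological features, and provides the machinery to study how
class-imbalance correction distorts such risk models. This vignette is the
package's account of the methods: the model, the preprocessing, every
tunable that matters, the synthetic data generator, and the numerical and
design choices that were genuinely open.

```{r setup}
library(gazerisk)
```

## The features

**Gaze entropies.** Fixations over the automation period are sorted into
rectangular spatial bins. With `p` the empirical distribution of fixations
over bins and `T` the empirical bin-to-bin transition matrix,

- stationary gaze entropy `Hs = -sum_i p_i log2 p_i` measures how widely
  gaze is dispersed;
- gaze transition entropy `Ht = -sum_i p_i sum_j T_ij log2 T_ij` (the
  conditional entropy of the fixation Markov chain, weighted by the
  stationary distribution) measures how unpredictable the scanpath is.

Both are normalised by the maximum entropy `log2(n_bins)` so they lie in
[0, 1], then z-scored across all trials of the dataset — in that order:
normalisation first, standardisation second. z-scoring is across trials,
not within participant, because the model treats trials as the analysis
unit and handles participants through clustered standard errors.

Choices made here, since a convention had to be fixed:

- **Log base.** Entropies are reported in bits (base 2). Normalisation by
  the maximum entropy makes every downstream quantity base-invariant, so
  the base is purely a reporting unit.
- **Ht normalisation.** The maximum conditional entropy per state is also
  `log2(n_bins)`, so Ht shares Hs's denominator.
- **Grid.** Default 8 x 8 over the unit square ([`bin_grid_regular()`]).
  Normalised entropies depend on the grid, so the grid is a reportable
  configuration item of every analysis, not a constant.
- **Binning convention.** Bins are half-open `[low, high)` with the last
  bin on each axis closed; a point exactly on an interior edge belongs to
  the higher-index bin. Points outside the grid are clamped to the nearest
  edge bin and tallied.
- **Dead rows.** Bins with no outgoing transitions contribute zero row
  entropy (the standard plug-in convention); their count is reported in
  the `entropy_result`.

A caveat worth knowing: with the stationary weighting above, the empirical
inequality `Ht <= Hs` is a property of trial-length scanpaths generated by
a fixation process, not a theorem about arbitrary label sequences. On very
short (tens of fixations), unstructured sequences the plug-in Ht can
exceed Hs by a few thousandths of a bit, because the row weights use the
full-sequence marginal rather than the transition-source marginal. At the
package's trial lengths (150+ fixations) the excess, when it occurs at
all, stays below 1e-4 bits across thousands of generated scanpaths; the
property suite asserts the inequality up to a 1e-3-bit allowance for this
estimation artifact.

**Pupil diameter.** The pipeline order is fixed: blink interpolation, then
zero-phase low-pass filtering, then averaging the eyes, then the window
mean, then dataset-level z-scoring. Blinks are linearly interpolated
between the nearest valid neighbours, independently per eye (so monocular
dropouts are handled correctly), with constant extension at trace edges;
the operation is idempotent. Smoothing is a Butterworth filter applied
forward and backward. Defaults — order 2, cutoff 4 Hz at 60 Hz sampling —
are conventional for pupillometry at this rate; both are configuration
items that appear in reports, not inferences from data. The zero-phase
pass is implemented with steady-state initial conditions and
odd-reflection padding so that constant signals pass through unchanged to
machine precision; generic forward-backward filtering without initial-state
handling leaves O(1e-3) edge transients, which matter when the feature is
a window mean.

## The model

For trial *i*: `Y_i ~ Bernoulli(P_i)`, with `logit(P_i)` a linear
combination of an intercept, Ht, Hs, Dm, all pairwise interactions, and
the three-way interaction — eight coefficients in a fixed column order.

**Maximum likelihood.** `fit_glm()` uses iteratively reweighted least
squares (tolerance 1e-10, at most 100 iterations). Fitted probabilities at
the 0/1 boundary or runaway coefficients are flagged as (quasi-)separation
and mark the fit non-converged; nothing fails silently. Conventional
covariance is the inverse observed information.

**Cluster-robust covariance.** Repeated measures make conventional
standard errors too small. `cluster_robust_vcov()` implements the
Liang-Zeger sandwich: scores `x_i (y_i - p_i)` summed within participants,
bread the inverse information, small-sample factor `G/(G-1)`. With
singleton clusters it reduces to the HC0 estimator times that factor —
a property the tests exploit, alongside a cross-check against
`sandwich::vcovCL()`. Confidence intervals are Wald; synthetic rows
created by rebalancing get fresh singleton cluster ids, mirroring the fact
that a synthetic observation belongs to no participant.

**Adaptive LASSO.** `fit_adaptive_lasso()` minimises
`deviance/n + lambda * sum_j w_j |beta_j|` over the non-intercept terms.
Design choices:

- *Initial estimator.* Weights are `1/|beta_ridge|` from an L2-penalised
  (ridge) logistic pilot fit (`adaptive_weights()`, default
  `ridge_penalty = 0.01` on the mean-deviance scale), weight exponent 1.
  Ridge is the natural pilot when predictors co-vary, as the two entropies
  do. Magnitudes are floored at 1e-8 before inversion.
- *Solver.* Accelerated proximal gradient (FISTA) with soft-thresholding,
  step size `2n / eigmax(X'X)`, adaptive restart, tolerance 1e-10 on the
  coefficient change, at most 10 000 iterations. At `lambda = 0` it
  reproduces the MLE to 1e-4 and at large `lambda` it collapses exactly to
  the intercept-only fit; the tests also verify agreement with glmnet's
  coordinate descent to 1e-6 across penalties — an independent algorithm
  for the same objective.
- *Penalty selection.* 100 log-spaced values from `lambda_max` (the
  smallest penalty zeroing all coefficients, from the subgradient
  condition at the intercept-only fit) down to `lambda_max * 1e-4`,
  stratified 5-fold cross-validation, minimum mean held-out binomial
  deviance, warm starts along the path.
- *No inference.* Penalised fits carry no covariance; `coef_table()`
  refuses them, because standard errors are not meaningful for LASSO-type
  estimates.

## Imbalance correction

Three regimes, each applied to the *fitting set only* and each producing
exactly equal class counts:

- `smote()`: synthetic collisions `x_i + lambda (x_zi - x_i)` with
  `lambda ~ U[0,1]`, `x_zi` one of the `k = 5` nearest minority neighbours
  of `x_i` (Euclidean distance on the three z-scored features; no internal
  re-scaling; the point itself excluded; distance ties broken by row
  order, which makes the neighbour sets seed-independent).
- `undersample()`: random majority deletion without replacement.
- `oversample()`: random minority duplication with replacement.

Test sets carry a `no_rebalance` marker that the correction functions
refuse, and `run_experiment()` additionally audits row ids, so leakage of
evaluation data into fitting data is structurally impossible rather than a
convention.

## Evaluation harness

One random 4:1 split (`floor(0.8 n)` fitting rows), then per regime and
model type: fit on the (corrected) fitting set, score on the untouched
test set.

- **Accuracy** at risk threshold .10; the boundary classifies positive.
  The threshold reflects asymmetric costs — a missed collision is far
  worse than a false alarm.
- **K-fold CV error** (K = 5, stratified, seeded) on the fitting set, with
  Brier score as the default cost; misclassification at 0.5 is available.
  "Prediction error" is ambiguous, so the choice is recorded in the
  report; Brier was chosen because it is a proper score and matches the
  error magnitudes such analyses report at ~10% prevalence.
- **ROC AUC** via the Mann-Whitney midrank formula (ties count 1/2),
  equal by construction to exhaustive pair counting, which the tests
  assert on all small inputs, plus a pROC cross-check.
- **Calibration intercept** (calibration-in-the-large): the intercept of a
  logistic regression of test outcomes on `logit(p_hat)` as a fixed
  offset (slope 1), with a Wald 95% CI. Zero means well calibrated;
  negative means risks were overestimated. Predictions at the boundary are
  clamped to `[1e-12, 1 - 1e-12]` and the clamp count reported.

The split is simple random by default ("randomly split" taken at face
value), with stratification available and flagged in the report. With 10%
prevalence and a test set of ~60 rows, a non-stratified split makes fit-
and test-set prevalence strongly anti-correlated, which roughly doubles
the spread of calibration intercepts for reasons that have nothing to do
with the model; the package's own simulation studies therefore stratify,
and say so.

## The synthetic-data generator

The generator exists so that every downstream stage has a testable truth.
It emulates a study of 38 participants with 8 analysable critical-takeover
trials each (~304 trials), two load conditions (a 2-back task dilates the
pupil by `load_pupil_effect = 0.3` mm and concentrates gaze,
`load_dispersion_effect = -0.1`), and ~10% collision prevalence.

Two continuous dials with known monotone maps onto the features:

- `dispersion` sets the stationary fixation distribution
  `pi = dispersion * uniform + (1 - dispersion) * point-mass`, so Hs grows
  monotonically with it;
- `randomness` mixes the transition kernel
  `K = (1 - randomness) I + randomness * 1 pi'`, so the chain's
  conditional entropy (Ht) grows with it, and `pi` is exactly stationary
  for `K`.

Per trial the dials are jittered (`dial_sd = 0.18`, clamped to
[0.02, 1]), the *true* normalised entropies are computed in closed form
from the kernel family (verified against the generic matrix formulas), the
true mean diameter adds trial noise (`pupil_trial_sd = 0.15` mm), features
are z-scored across the dataset, and the collision is drawn from
`Bernoulli(plogis(X beta + u))` with `u` a participant-level shift
(`cluster_sd = 0.5` by default) and `beta` defaulting to the published
uncorrected-data estimates (`default_beta()`). Raw signals — a Markov
fixation sequence over the grid with gamma durations (mean ~0.4 s, so
~300 fixations fill a two-minute automation period), and a 60 Hz binocular
pupil trace with a shared ~1 s-time-constant drift (SD 0.1 mm), small
independent per-eye noise, and Poisson blinks (15/min, 150 ms) marked
invalid with `NA` diameters — are generated to match each trial's dials,
so the feature-estimation pipeline can be checked against the truth table.

Collisions occur only on short time-to-collision (`ttc3`) trials. The
generator enforces this by drawing the outcome from the logistic model for
every trial and labelling collision trials `ttc3` (filling the remaining
half-quota at random), rather than by restricting the Bernoulli draw to a
predetermined `ttc3` half. The latter would either halve the prevalence or
break the identity between the generating coefficients and what a
logistic fit on the full table estimates; with the chosen construction the
generating coefficients are exactly recoverable, which the tests verify at
n = 20 000 within 3 standard errors, and the implied conditional collision
rate among `ttc3` trials (~20%) matches the arithmetic of the emulated
study.

What the generator does *not* emulate: saccade dynamics and fixation
classification (it produces fixations directly), vehicle dynamics and
braking reaction times, luminance effects on the pupil, non-critical
filler events, and trial exclusions. Passing tests therefore demonstrate
that the pipeline is correct and that the calibration phenomena are real
consequences of rebalancing — not that any particular real dataset will
show effects of the same size.

## Simulation results the package asserts

With generating coefficients set to the published estimates and no
participant clustering (`cluster_sd = 0`, under which the marginal
prevalence is the stated ~10%; the participant shift inflates it to
~11.5%), over 50 seeded replicates of the full pipeline with a stratified
split:

- uncorrected fitting keeps the test-set calibration intercept inside
  (-0.5, 0.5) in well over 80% of replicates;
- SMOTE, under- and over-sampling all produce intercepts below -1 with
  CIs excluding 0 (risk overestimation) in over 80% of replicates;
- uncorrected fitting beats every rebalanced regime on threshold accuracy
  in over 80% of replicates.

Wald CI coverage is checked at 0.95 +/- 0.03 over 500 fits of ~1000
trials each; n = 1000 rather than ~300 because at 10% prevalence and eight
parameters the small-sample bias of Wald intervals — a property of the
interval, not the implementation — would otherwise dominate the check.

One pattern from the motivating analysis does **not** replicate and is
deliberately left failing in the acceptance suite: that penalised models
lose less threshold accuracy than standard models under rebalancing. At a
uniform .10 threshold both model types fitted to balanced data predict
near 0.5 for everything and collapse to near-prevalence accuracy, so the
ordering is a coin flip. The source's penalised accuracies are
arithmetically consistent with classification at a 0.5 threshold (its
best penalised uncorrected accuracy equals the majority-class share of a
59-row test set), i.e. with a different threshold convention for the two
model types; the package applies one threshold to all cells and documents
the discrepancy rather than reproducing it.

## Problem sizes

The test suite generates everything it needs at run time: entropy oracles
on 200 random short sequences, chain-convergence checks at 50 000
fixations, the 50-replicate directional studies at the study's own scale
(304 trials), coefficient recovery at 20 000 trials, and coverage over 500
fits. The acceptance script's grid runs one full synthetic study (304
trials, both model types, all four regimes).

## Known limitations

- Fixation classification from raw gaze is out of scope; inputs are
  fixation sequences.
- No multilevel (random-effects) models: with synthetic singleton
  "participants" created by rebalancing, random-intercept structures are
  unstable, which is the very reason the fixed-effects-plus-clustered-SE
  design exists. Consequently, with clustering present, fitted
  coefficients are marginal (population-averaged) and mildly attenuated
  relative to the generating conditional coefficients (~4% at
  `cluster_sd = 0.5`).
- The calibration harness estimates the intercept only; calibration
  slopes and flexible calibration curves are not implemented.
- Printed-grid choices (8 x 8 bins, 4 Hz/order-2 smoothing) are
  conventions to be reported, not recoverable properties of data.
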
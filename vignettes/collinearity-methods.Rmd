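---
title: "Multicollinearity and binary clinical prediction models: models, generators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicollinearity and binary clinical prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In low-dimensional clinical prediction modelling — for instance normal-tissue
complication probability (NTCP) models that predict xerostomia or dysphagia
risk after head-and-neck radiotherapy from clinical characteristics and
organ-at-risk (OAR) dose metrics — predictors are often strongly collinear:
dose metrics of the same organ, or of neighbouring organs, carry largely the
same information. Collinearity inflates the variance of maximum-likelihood
coefficients without necessarily harming prediction, so a model may predict
well while individual coefficients look clinically implausible (zero or
negative dose effects), undermining face validity and, in treatment-plan
optimization, potentially steering dose toward organs whose coefficients
happened to come out small.

`collinsim` provides the machinery to study this quantitatively: a generator
of multivariate-normal predictor data with *calibrated* collinearity, a
logistic ground-truth outcome model with calibrated prevalence and
discrimination, eight estimation methods on a shared optimization core,
likelihood-based hyperparameter tuning, and repeated-simulation evaluation of
discrimination (AUC), calibration (intercept/slope), overall fit (Nagelkerke
R²), coefficient error (MAE), and predictor-selection stability (MJICS, the
mean Jaccard index of thresholded coefficient signs across repetitions).

## Data-generating model

Predictors are drawn from `MVN(0, R)` where `R` is a block-exchangeable
correlation matrix: `n_clinical` weakly correlated clinical predictors
(pairwise r = 0.1, also with the dose predictors) plus dose blocks with a
common within-block correlation and a between-block correlation. Means are 0
and variances 1 without loss of generality, since all modelling happens after
standardization.

Collinearity is quantified by the median variance inflation factor: for
standardized predictors, `VIF_j = [R^{-1}]_{jj}`. The generator calibrates
`R` to a target median VIF by bisection along a one-parameter convex path —
toward the identity to de-correlate, or toward the same block pattern with
within-block correlation 0.995 to amplify — with an eigenvalue-floor /
diagonal-renormalization repair after every step. The bisection tolerance is
1% relative; the saturation endpoint bounds the attainable range and
unreachable targets are an error, not a silent clip.

The outcome follows a logistic model `P(y=1|x) = plogis(b0 + x'theta)`.
Two ground-truth modes exist:

* **draw** — clinical coefficients from `N(0, 0.3^2)`, dose coefficients from
  `|N(0, 0.2^2)|` (dose to healthy tissue does not reduce complication risk),
  rescaled by one common factor so the true-model AUC is 0.75 ± 0.01 on a
  large Monte-Carlo sample. This mode is used for controlled
  parameter-recovery tests.
* **ridge_distill** (default) — the drawn model generates a 10,000-record
  seed dataset, and a mildly ridge-penalized logistic fit to that dataset is
  adopted as the truth. This mimics a ground truth obtained by penalized
  regression on an observed cohort: coefficients inherit the sampling
  correlation structure instead of being an idealized draw.

The intercept is calibrated by bisection so the Monte-Carlo mean risk over
200,000 draws matches the setting's target prevalence within 1e-3. Target
prevalences come directly from the settings catalogue as
`target_events / n_dev`, so events-per-variable (EPV) is matched exactly per
setting (A: 161/592 at p = 7 gives EPV 23; D: 86/592 at p = 43 gives EPV 2).

The shipped catalogue (`default_settings()`) has eight settings: two outcomes
(xerostomia: p = 7 and 19; dysphagia: p = 13 and 43), each with a
low-collinearity variant (median VIF 5 or 7) and a high-collinearity variant
(median VIF 43), all at development size n = 592 and validation size 10,000.

What the generator deliberately does *not* emulate: non-Gaussian predictor
marginals (real dose-volume metrics are bounded and skewed), nonlinear
predictor-outcome relations, measurement error, and missingness. Passing
tests therefore speak to the behaviour of the estimators under Gaussian
collinearity of a given strength, not to every property of real cohort data.

## The eight estimators

All methods model `P(y=1|x) = plogis(b0 + x'beta)` on standardized predictors
and report coefficients on that scale. The per-record objective is

```
mean NLL + (lambda_l1 * ||beta||_1 + lambda_l2 * ||beta||^2) / n
```

with the intercept never penalized, dropped, or constrained. Scaling the
penalty by `1/n` keeps a given `lambda` value's shrinkage effect interpretable
as a prior whose influence fades with sample size, and maps directly onto the
coordinate-descent convention of `glmnet` (`lambda_glmnet = lambda / n`),
which the tests exploit as an independent oracle.

* **LR** — plain maximum likelihood.
* **Ridge / Lasso / ElasticNet** — quadratic and/or absolute penalties; the
  l1 part is handled by a proximal soft-threshold so exact zeros are
  attainable (important because selection stability is scored on thresholded
  signs).
* **Dropout** — at each training iteration every predictor is zeroed
  independently with probability `delta` and retained columns are rescaled by
  `1/(1-delta)` (inverted dropout); the final weights are used unscaled at
  prediction. In expectation this behaves like a data-adaptive quadratic
  penalty and discourages coefficient co-adaptation.
* **PCLR** — logistic regression on the top `d_pca` principal-component
  scores (eigenvectors of the sample correlation matrix, descending
  eigenvalues, each loading's largest-magnitude entry made positive),
  back-projected to an equivalent model on the original predictors
  (`beta = V gamma`; the intercept is unchanged because scores are
  zero-mean).
* **LAELR** — a linear autoencoder whose training criterion is the outcome
  likelihood plus `lambda_lae` times the mean squared reconstruction error,
  so the components are chosen jointly for reconstruction and prediction; a
  compromise between PCLR (`lambda_lae -> Inf`, components span the principal
  subspace) and LR (`lambda_lae = 0` with full `d_lae`). The decoder is tied
  to the encoder transpose. Tying is a deliberate choice: with an untied
  decoder and perfectly collinear predictors only the *sum* of the
  corresponding encoder rows is identified, so the back-projected
  coefficients of collinear predictors would retain the arbitrary asymmetry
  of the random initialization — exactly the kind of instability the method
  is supposed to avoid.
* **LR_NN** — maximum likelihood with dose-type coefficients constrained
  non-negative by projection (clipping at zero) after every gradient step;
  the hard-constraint counterpart of the clinical prior encoded in the
  generator's `nonneg_mask`.

## Numerical choices

The shared solver is monotone proximal gradient descent with
Barzilai–Borwein steps and backtracking line search, run to a relative
objective change below 1e-8 sustained over 10 iterations (at most 10,000).
The l1 term and the non-negativity constraint live in the proximal map, which
gives exact zeros and exact projections and satisfies the optimality
conditions at the fixed point. A constant-step adaptive-moment scheme was
considered and rejected: with a fixed step it limit-cycles around the optimum
at an amplitude proportional to the step, which breaks both objective
monotonicity and the tight equivalences the test-suite checks (e.g. Ridge
with zero penalty matching LR to 1e-4, the Lasso path matching coordinate
descent to 1e-3).

Dropout training is constant-step proximal SGD (step `(1-delta)^2 / L`, with
`L` the curvature bound of the rescaled data). Because its objective is
stochastic, the deterministic stopping rule never fires; instead training
stops when a 200-iteration window of the masked objective shows no material
improvement (1e-4 relative) over the previous window, capped at 4,000
iterations. With `delta = 0` Dropout's objective *is* the LR objective and it
is fitted by the deterministic path. LAELR uses the same BB scheme on its
joint nonconvex objective with seeded `N(0, 0.1^2)` initialization; with a
backtracking safeguard the objective is monotone even when the BB step is
optimistic.

Positive-definiteness repair is an eigenvalue floor (1e-6) followed by
diagonal renormalization — simple, deterministic, and testable; a
nearest-PD projection would be less transparent in how it perturbs the
off-diagonals.

## Tuning

Hyperparameters are tuned by sequential model-based optimization of the mean
held-out log-likelihood under stratified 3-fold cross-validation, with
standardization refit inside every training fold. Domains: `lambda_*`
log-uniform on `[1e-5, 1e3]`, `delta` uniform on `[0, 0.9]`, component counts
integer-uniform on `[1, p]` — wide enough that the end points (effectively
unpenalized and total shrinkage) are both reachable. The first five
evaluations are a maximin Latin hypercube; the remainder are
expected-improvement proposals from a Gaussian-process surrogate
(squared-exponential kernel, fixed lengthscale 0.25 on the unit cube, small
nugget), maximized over random candidates plus local perturbations of the
incumbent. Every iteration is independently seeded so a longer budget extends
a shorter run's evaluation sequence instead of altering it, and a pure
random-search optimizer sits behind the same interface for testing. The
default budget is 30 evaluations (15 in the scaled-down test configuration) —
the criterion surfaces here are low-dimensional (1–2 parameters) and smooth,
where a handful of guided evaluations suffices.

Tuning receives only the development dataset; the validation sample never
enters tuning or fitting. That independence is asserted in the test-suite by
changing the validation stream and checking that every fitted coefficient is
bit-identical.

## Evaluation

Validation metrics per repetition: Mann–Whitney AUC (half-credit ties),
calibration intercept (maximum-likelihood intercept of a logistic model with
the predicted logit as offset — calibration-in-the-large), calibration slope
(logistic recalibration slope), and Nagelkerke R². Coefficient MAE/MSE are
computed against the generating coefficients on the standardized scale,
intercept excluded.

Selection stability uses the thresholded sign function (`+1` above 0.01,
`-1` below −0.01, else 0 — i.e. "excluded") and the Jaccard index of the
(index, sign) pair sets of two fitted coefficient vectors; MJICS averages the
index over all unordered pairs of the repetitions. Two semantics are
defensible when both models exclude a predictor: the default treats zeros as
non-elements (the index scores only *included* coefficients; two all-excluded
models score 1 by convention), while `count_zero_agreement = TRUE` treats
shared exclusion as agreement. The default follows the "included
coefficients" reading; the flag exists because the formal set definition
alone does not resolve it.

Summaries are means with simple percentile intervals (2.5/97.5 for 95%) over
repetitions — the repetition distribution is directly available, so no
normal approximation is needed.

Calibration curves are plain (non-robust) lowess smooths of outcome against
predicted risk: the robustness reweighting of classical lowess assumes
unimodal residuals and visibly biases the curve for binary outcomes.

## Study orchestration and problem sizes

`run_study()` executes, per setting and repetition: child-seed derivation
(counter-based splitting of the master seed, so simulation, tuning, and
stochastic fits draw from disjoint streams), development and validation
simulation, per-method tuning and refitting, and validation scoring; MJICS is
computed per method after the last repetition. A failed repetition is
re-drawn with a fresh child seed (at most 3 retries). Degenerate per-metric
failures (e.g. a calibration slope of a constant-risk model) are recorded as
`NA` rather than failing the repetition.

The package ships two scales. The paper-scale configuration (8 settings ×
100 repetitions × budget 30, validation 10,000) reproduces the full design
and runs for hours. The test-suite and the replication checks use the reduced
configuration — settings A/A_hi and C/C_hi, 25 repetitions, budget 15 —
which preserves every qualitative contrast (low vs high collinearity at high
and moderate EPV) at roughly 1/20 of the cost; the reduced study's findings
are asserted directionally (differences and rankings), not as point values.

## Known limitations

* The block-exchangeable correlation emulation reproduces the *strength* of
  collinearity (median VIF) but not the idiosyncratic correlation geometry of
  a real dose-metric covariance matrix; results about methods' relative
  stability transfer, absolute MJICS values need not.
* The ridge-distilled ground truth uses a fixed mild penalty; a tuned
  distillation penalty would slightly change the true coefficient spectrum.
* MJICS compares models fitted to independent replicates of the same
  distribution; it does not measure stability under distribution shift.
* The Bayesian-optimization surrogate uses fixed kernel hyperparameters;
  for the 1–2 dimensional spaces here this is adequate, but the tuner is not
  intended as a general-purpose optimizer.
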
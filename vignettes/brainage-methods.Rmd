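---
title: "Morphometric brain-age modelling and comorbidity inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric brain-age modelling and comorbidity inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`morphage` implements a complete normative brain-age analysis for
network-wise cortical morphometry: 28 features (cortical thickness, sulcal
depth, surface area, cortical volume, each summarised within the seven
canonical cortical networks VIS/SMN/DAN/VAN/LIM/FPN/DMN) are harmonized
across scanners, mapped to chronological age with Gaussian-process
regression trained on a healthy cohort, and converted to a bias-corrected
brain-age gap (BAG) per participant. Downstream, the package provides
dose-dependent group models of BAG over a disorder-burden factor (0, 1 or
2 of HIV infection and chronic cocaine use), logistic models of
neurocognitive impairment (NCI), a bootstrap path model for BAG-mediated
impairment, signed Shapley attribution of each prediction to the 28
features against age-matched reference baselines, and mixed-effects tests
of how disorder burden shifts those attributions. A synthetic-cohort
generator with planted effects gives every stage a ground-truth recovery
test; no imaging data are read — the pipeline begins at the extracted
feature table.

# The normative age model

## Gaussian-process regression

Features are standardized to training means and SDs, the age target is
centred, and the covariance is

$$k(x, x') = \sigma_f^2 \exp\!\left(-\tfrac{\lVert x - x'\rVert^2}{2\ell^2}\right)
  + \sigma_l^2\, x^\top x' + \sigma_n^2\,\delta_{x x'},$$

a squared-exponential term for smooth nonlinear ageing, a linear term for
the global trend, and white noise. Predictions are the usual posterior mean
$m(x_*) = k_*^\top (K + \sigma_n^2 I)^{-1} y$. The four hyperparameters are
optimized on the log scale by L-BFGS-B with analytic gradients of the log
marginal likelihood, from a data-driven start plus seeded random restarts
(default 5; box constraints $e^{\pm 15}$). Cholesky factorization is
attempted on the exact matrix first; if it fails, jitter starting at
$10^{-8}\,\overline{\mathrm{diag}(K)}$ is escalated tenfold up to
$10^{-2}$. This keeps the fitted model within testing distance (1e-8) of a
dense-matrix oracle on well-conditioned problems, which an unconditional
jitter would not.

## Cross-validation and age-bias correction

Model accuracy is assessed by k-fold cross-validation (default 5) with
fold assignment stratified by age quantile, which stabilises per-fold MAE.
Because regression predictions shrink toward the training mean, the raw
gap (predicted minus chronological age) correlates negatively with age;
the correction fits `gap ~ beta0 + beta1 * age` by OLS on the pooled
out-of-fold training predictions and subtracts the fitted trend. This
variant (rather than rescaling predicted age) leaves the training-set
corrected gap *exactly* orthogonal to age, a property the test suite
checks to 1e-10. Corrections are always estimated on the training cohort
and applied unchanged to clinical data; estimating them on the evaluation
cohort would absorb real group differences.

## Accuracy metrics

MAE and the squared Pearson correlation between chronological and
predicted age, overall and per group. Squared correlation is sign-blind —
perfectly anti-correlated predictions also score $R^2 = 1$ — which is
documented rather than patched, since the estimator is standard in this
literature.

# Harmonization

Scanner effects are removed with the canonical parametric empirical-Bayes
location/scale model: per-feature regression on batch indicators plus a
protected biological design (age, sex, disease status), standardization by
pooled residual variance, then shrinkage of per-batch means toward a
normal prior and per-batch variances toward an inverse-gamma prior, both
moment-estimated across features. The implementation is in-package because
the pipeline must support *fit on one cohort, apply to another* (the
clinical cohort may arrive later, on its own scanner); the test suite
verifies that a joint fit agrees with the established reference
implementation to numerical precision, that planted offsets are removed
(post-harmonization batch F below the 5% critical value in at least 27/28
features), that planted age slopes survive within 5%, and that the
operation is approximately idempotent. When cohorts are harmonized
jointly, disease status enters the design as the disorder count with
healthy-cohort rows coded 0, so disease variance is preserved rather than
scrubbed along with the scanner effect. Joint fitting is the default;
train-then-transform is available through the same fit/apply split.

# Shapley attribution

Each clinical prediction is attributed to the 28 features with an
interventional value function: the value of a coalition S is the mean
model prediction over k = 10 training participants nearest in age to the
target (ties broken by participant id), with the features in S replaced by
the target's values. The baseline is the mean prediction over the
reference rows, so positive values are contributions toward older
predicted age, in years. Values are estimated by antithetic permutation
sampling (default 512 permutations, seeded); contributions telescope along
each permutation, so the efficiency identity
$\sum_j \phi_j = f(x) - \text{baseline}$ holds by construction, and
Monte-Carlo standard errors come from the spread of antithetic-pair
averages. An exact enumerator over all $2^d$ coalitions (feasible to
d = 15) serves as the oracle: the dummy and symmetry axioms hold exactly
there, and sampled values must land within 3 MC SEs of it. With 28
features exact enumeration ($2^{28}$ coalitions) is infeasible, hence the
sampling estimator; the reference-set size and the estimator are declared
conventions of this package.

# Cohort inference

* **NCI classification**: impaired iff at least 2 domains have T-scores at
  or below mean − 1 SD. The boundary is inclusive: exactly T = 40 counts.
* **Group models**: OLS of BAG (or a single feature) on the burden factor
  plus covariates (age, sex, education, Zung depression score, Euler
  number, head motion); Type III F via sum-to-zero contrasts
  (`car::Anova`), all pairwise contrasts with Benjamini–Hochberg
  adjustment.
* **Logistic models**: ML logistic fits with likelihood-ratio chi-squares
  for the focal term, Wald CIs on odds ratios, and model-adjusted
  impairment probabilities by marginal standardization (G-computation:
  every participant's exposure set counterfactually to each level,
  predictions averaged) with seeded percentile-bootstrap CIs.
  At-covariate-means adjustment was rejected as less interpretable for a
  binary outcome. Quasi-separation is detected and flagged with a warning
  rather than silently re-penalized.
* **Factorial models**: `outcome ~ hiv * cu + covariates` with Wald
  chi-squares per term; an empty exposure cell drops the inestimable
  interaction with a warning.
* **Mediation**: a two-equation path model — linear BAG equation, and a
  linear-probability outcome equation — so that total = direct + indirect
  holds *exactly* on every draw and standardized coefficients
  (effect × sd(exposure)/sd(outcome)) are well defined. A probit/logistic
  outcome link would break that identity; exact decomposability was chosen
  because it is testable and because bootstrap inference (seeded
  percentile CIs over participants, default 2000 draws, including the
  between-contrast difference in indirect effects) does not rely on the
  link. The known cost is that the outcome equation is a linear
  approximation to an intrinsically nonlinear risk model.
* **Exact Fisher tests**: 2 × C tables with total ≤ 500 are evaluated by
  full enumeration of margin-constrained tables under the two-sided
  probability-ordering rule (matching the convention, including the
  relative tolerance, of the network algorithm); larger or higher-order
  tables use `stats::fisher.test`.
* **Mixed-effects tests on signed attributions**: random-intercept-per-
  participant linear mixed models of the 28 signed values with fixed
  effects for burden, network, measure and all interactions plus
  covariates. Coefficients and variance components by REML; fixed-term
  inference by likelihood-ratio tests between ML fits of nested models.
  Denominator-df approximations (Satterthwaite/Kenward–Roger) are
  deliberately not used: they are software-convention-specific, whereas
  LRT calibration can be (and is) verified by simulation. Follow-ups test
  burden × network within each measure and the burden effect within each
  network-measure cell (participant-level OLS, one row per participant per
  cell), with BH correction within measure and within cell respectively.

# The synthetic-cohort generator

The generator is first-class, tested code; its defaults are the study
conditions every recovery test runs under.

* **Cohorts**: 725 training participants aged 36–100 (uniform), clinical
  groups of 34/72/80 aged 35–77 carrying 0/1/2 disorders; the 1-disorder
  group splits evenly into HIV-only and cocaine-only.
* **Features**: each feature follows
  `baseline + slope·(effage − centre) + curvature·(effage − centre)² +
  burden·group + site offset + noise`, where *effective brain age* is
  chronological age plus the participant's latent brain-age deviation.
  Baselines and scales are conventions at plausible magnitudes (thickness
  ~2.5 mm, sulcal depth ~10 mm, areas ~1.2e4 mm², volumes ~1.1e4 mm³) —
  the source study reports no feature-level moments, so absolute scales
  are not calibrations — and they deliberately span four orders of
  magnitude so standardization is genuinely exercised. Age slopes carry
  measure-specific network weights chosen to mirror the qualitative
  pattern of network-wise cortical ageing (thickness strongest in
  ventral-attention/default-mode cortex, sulcal deepening dominated by
  somatomotor cortex, surface-area loss by limbic cortex).
* **Latent BAG**: healthy training participants deviate from their
  chronological age with SD 3 years (default); clinical participants
  deviate by their group offset (0/3.5/6.3 years) plus noise with SD 2
  years. Because all features are generated at effective brain age, a
  well-fitted normative model recovers the planted offsets through the
  full pipeline, attenuated only mildly by shrinkage. A separate
  *accuracy regime* with healthy-deviation SD 8 reproduces study-scale
  cross-validated error (MAE ≈ 5–6 years); it is not the default because
  larger healthy deviations attenuate clinical offset recovery — the two
  regimes answer different questions and are reported separately.
* **Burden pattern**: defaults lower thickness in VIS/VAN/FPN and deepen
  SMN sulci per disorder, matching the direction of the comorbidity
  effects the pipeline is designed to detect. Their magnitudes are kept
  small (0.1 residual SD per disorder) so the *total* planted group BAG
  remains the stated 0/3.5/6.3 years: these offsets act through the model
  in the ageing direction, and larger values would make the generator
  plant more BAG than it claims.
* **Outcome**: NCI is Bernoulli with log-odds
  `−1.54 + 0.08·trueBAG + 0.55·group + 0.02·(zung − 41) + 0.3·education`,
  planted directly from the *true* latent BAG, not the fitted model, so
  mediation recovery is a pure statistics test independent of GP quality.
  The slope 0.08/year matches an odds ratio of ≈1.08 per BAG year; the
  direct effect is linear per disorder, which cannot reproduce a
  plateau-shaped odds pattern across 1 vs 2 disorders — a known limit of
  this generative family.
* **T-scores**: unimpaired domains are Normal(50, 10); planted-impaired
  participants draw ≥2 domains from Normal(34, 3), i.e. 2 SD below the
  T = 40 cut, so planted impairment is reliably detectable by the
  classification rule (a mean of 38 would leave individual domains above
  the cut a quarter of the time and make the planted flag unrecoverable).
  Under the null the rule's false-positive rate is substantial (~0.3 with
  7 independent domains), which mirrors its behaviour on real batteries.
* **What the generator does not emulate**: between-feature covariance
  beyond shared age, latent BAG and site terms; non-uniform age
  distributions; missingness; scanner drift over time. Passing recovery
  tests therefore demonstrates correctness of the estimators under the
  stated generative family, not robustness to real-data pathologies.

# Numerical choices and problem sizes

Simulation-based checks use sizes chosen to balance statistical
resolution against a desk-scale run: full-pipeline dose-response recovery
uses a 300-participant training fit with 200 participants per clinical
group, plus 200 regenerated cohorts (training n = 150) scored with the
reference fit's hyperparameters and a per-replicate posterior refit;
mediation null-coverage uses 300 replicates of n = 600 with 200 bootstrap
draws each; type-I-error calibration uses 500 null replicates per test,
with the mixed-model calibration at 120 participants (28 rows each) —
likelihood-ratio tests of a 36-df interaction need cohorts of roughly
this size before their asymptotic reference applies, and smaller designs
were measurably anticonservative. GP oracle agreement is exercised on 100
random instances with n ≤ 50. The acceptance script runs the study-scale
configuration (training n = 725, clinical 34/72/80) once per regime.

Ties in reference-set selection break by ascending participant id;
fold assignment, restarts, bootstraps and permutation sampling are all
seeded; bootstraps resample participants, never rows of the long
attribution table, to respect within-participant clustering.

# Known limitations

* The linear-probability mediation equation can predict outside [0, 1] in
  extreme covariate ranges; estimates remain valid least-squares
  projections, but individual predicted risks should not be read off it.
* Hyperparameter optimization is multi-start local ascent; with few
  restarts on small cohorts it can settle in a local optimum. The restart
  count and seed are recorded in the model object.
* The sampling Shapley estimator's error scales as the reported MC SE;
  strongly interacting feature sets need more permutations.
* Group-wise $R^2$ on small groups is noisy and is reported without
  uncertainty.
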
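---
title: "EEG-fMRI fusion measures of error monitoring and longitudinal anxiety models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-fMRI fusion measures of error monitoring and longitudinal anxiety models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionern)
```

## The scientific problem

The error-related negativity (ERN) is a frontocentral negative-going EEG
deflection that follows error responses and is larger than after correct
responses.  Its main cortical generators are the dorsal anterior cingulate
cortex (dACC) and the posterior cingulate cortex (PCC), whose relative
contributions shift across adolescence.  A long-standing question is whether
error-monitoring activity in these regions helps anticipate how anxiety
symptoms will change across adolescence, particularly in youths with a
temperament history of behavioral inhibition (BI).

EEG has the temporal precision to isolate the ERN but poor spatial
resolution; fMRI resolves dACC from PCC but cannot isolate a
response-locked component.  This package implements a multiplicative
*EEG-fMRI fusion* measure that conditions EEG source estimates on fMRI
error contrasts, and the longitudinal statistical chain built on it:
two-wave latent change score (LCS) models estimated by full-information
maximum likelihood (FIML), a blockwise incremental-validity model, a
focused moderated path model, and simple-slopes probing.  Because the
underlying cohort data are not public, the package ships a synthetic-cohort
generator that reproduces the *structure* of such a study, so every stage
is testable and the statistical machinery can be calibrated by parameter
recovery.

## The fusion measure

Per subject and wave:

1. Condition-average ERPs are formed for incongruent-error and
   incongruent-correct trials, and the ERN peak is the time at which the
   frontocentral cluster mean of the error-minus-correct difference wave is
   most negative within a post-response window (default 0-100 ms).
   "Maximal" is interpreted as greatest negative polarization; exact ties
   resolve to the earliest sample so output is deterministic.
2. Current density reconstruction (CDR) values live on a tetrahedral
   source mesh; subtracting the correct-trial map from the error-trial map
   gives the CDR difference map at the ERN peak.
3. Each fMRI contrast voxel (error minus correct) that overlaps the mesh
   is multiplied by the CDR-difference value of the tetrahedron containing
   it; the products are the fusion scores.

Three operational choices deserve comment, because "overlap" is not
uniquely defined when a 3-mm voxel grid meets a finer tetrahedral mesh:

* **Containment, not partial volume.**  A voxel belongs to the element
  containing its centroid (barycentric coordinates, tolerance `1e-9`).
  This is deterministic, cheap, and consistent with using unsmoothed,
  uninterpolated contrasts.  A centroid sitting exactly on a shared face
  is assigned to the containing element with the lowest index.
* **Symmetric rule for the mesh side.**  An element belongs to a region of
  interest (ROI) when its centroid falls in an ROI-labeled voxel.
* **Unmapped voxels are excluded** from fusion ROI means rather than
  zero-filled; zero-filling would bias means toward zero wherever mesh and
  grid fail to intersect.

ROI scores are means over the dACC and PCC masks: the EEG-only score is
the mean CDR difference over in-region elements, the fMRI-only score the
mean contrast over in-region voxels, and the fusion score the mean product
over in-region mapped voxels.  A fusion score exists only when both
modalities do; an empty contributing set yields a missing value carrying a
reason attribute, never a silent zero.

## The FIML SEM engine

All models are mean-and-covariance structures in the "all-y" LISREL
parameterization,

$$y = \nu + \Lambda\eta + \varepsilon, \qquad
  \eta = \alpha + B\eta + \zeta,$$

with implied moments
$\mu = \nu + \Lambda(I-B)^{-1}\alpha$ and
$\Sigma = \Lambda(I-B)^{-1}\Psi(I-B)^{-\top}\Lambda^\top + \Theta$.
Each matrix cell is free, fixed, or equality-constrained via a shared
label, so measurement-invariance constraints hold exactly by construction.

The log-likelihood is the casewise Gaussian density of each subject's
observed subvector, grouped by missingness pattern and evaluated from
per-pattern sufficient statistics, so incomplete cases are retained
(FIML).  Numerical choices:

* start values: free loadings 1, intercepts at sample means, residual
  variances at half sample variances, structural paths 0; model builders
  override these with method-of-moments starts;
* quasi-Newton optimization (`nlminb`, relative tolerance `1e-10`) with up
  to 5 seeded-jitter restarts on non-convergence; a non-positive-definite
  implied covariance returns a finite penalized value so the optimizer can
  retreat;
* a pre-fit identification check: the implied-moment Jacobian must have
  full column rank at (jittered) start values;
* standard errors from the inverse observed information, differentiated
  numerically at the optimum; 95% CIs are $\pm 1.96\,\mathrm{SE}$ and
  p-values two-sided normal, matching the symmetric intervals such studies
  report;
* fit indices (RMSEA, SRMR, CFI) are plain maximum-likelihood variants —
  robust corrections are out of scope — and are reported as not applicable
  when a model is just-identified.

For just-identified models (the saturated model, the path models) the
exact FIML solution is computed directly: expectation-maximization for the
unstructured Gaussian moments, then the closed-form transform to model
parameters.  This is algebraically the same maximum, obtained without
high-dimensional numerical optimization.

## The latent change score models

**Anxiety.**  At each wave (ages 13 and 15) anxiety is a latent factor
with three indicators: parent-report SCARED total (the marker, loading
fixed to 1), child-report SCARED total, and a binary any-anxiety-diagnosis
indicator.  The wave-2 latent is the sum of the wave-1 latent and a latent
change factor (both structural paths fixed to 1); the change factor's mean
and variance are the quantities of interest.  Unstandardized loadings are
constrained equal across waves; indicator *intercepts* are constrained
equal as well, which the measurement-invariance statement alone leaves
open but which is required for the mean structure to be identified — this
is a deliberate design decision.  The binary diagnosis is treated as a
continuous 0/1 indicator under normal-theory ML (the common default in
applied SEM); this attenuates its loading but leaves the latent scale,
anchored by the parent-report marker, essentially untouched.

**Neural.**  Each modality-by-region score pair (wave 13, wave 15) enters
a single-indicator two-wave LCS with residual variances fixed to 0 — the
only identifying convention available for two waves of one indicator.
With complete data this model reproduces the classical difference score
exactly (a property the tests assert); with a missing wave, FIML retains
the subject and the factor score is the model-based conditional
expectation, flagged as such.

**Standardized change.**  The change factor's mean and variance are
reported relative to the implied wave-2 latent scale:
$\mathrm{std(mean)} = \mu_\Delta / \mathrm{SD}(\eta_{15})$ and
$\mathrm{std(var)} = \sigma^2_\Delta / \mathrm{Var}(\eta_{15})$ with
$\mathrm{Var}(\eta_{15}) = \sigma^2_{13} + \sigma^2_\Delta +
2\,\mathrm{cov}$.  This convention makes change comparable across regions
and modalities measured in arbitrary units, and it is the convention under
which the generator's default unstandardized values imply a standardized
dACC fusion change of 0.37.

## Blockwise incremental validity

The incremental question — does each neural modality explain anxiety
change beyond what came before? — is answered by entering predictors in
four fixed blocks: (1) sex, minority status, BI, baseline anxiety;
(2) EEG-only ROI baseline/change scores and their BI products; (3) the
same for fMRI; (4) the same for EEG-fMRI fusion.  The estimand for block
$k$ is the semipartial multiple correlation $\gamma_k$ of the block with
the outcome after removing all earlier blocks, so $\gamma_k^2 =
\Delta R^2_k$ and the increments sum to the total $R^2$.

Internally the package estimates the joint predictor/outcome moments by
FIML (EM) and derives the $\gamma_k$ from the fitted covariance matrix.
For a just-identified model this is the exact ML solution, and on complete
data the increments equal hierarchical OLS $\Delta R^2$ to machine
precision — that equivalence is the normative contract, asserted at
`1e-6` in the test suite.  The phantom-variable path parameterization of
the same estimand (exogenous $\varepsilon$'s feeding block factors
$\omega_1 \ldots \omega_4$, sequentially orthogonalized) produces
identical estimates; the moment route avoids optimizing hundreds of
auxiliary parameters.

**Testing an increment.**  A Wald z-statistic on a single $\gamma_k$
degenerates under the null for multi-predictor blocks: with sequential
orthogonalization $\hat\gamma_k \ge 0$ almost surely, so its null
distribution is not normal.  The package therefore tests the increment
itself with the F-form statistic (numerator df = block size), which on
complete data is the classical hierarchical-regression test of the same
hypothesis and is finite-sample calibrated under normality — the test
suite verifies the 5% type-I rate over 400 null replicates.  A
delta-method SE for $\gamma_k$ (Wishart covariance of the fitted moments)
is still reported for effect-size interpretation.

**Outcome scores.**  The outcome is the anxiety change factor score
extracted from the anxiety LCS, and baseline anxiety enters block 1 as the
extracted wave-1 score.  This keeps the incremental and path models
just-identified — consistent with reporting no fit indices for them — and
mirrors extracting change scores from the neural LCS fits.  All predictors
are z-scored before entry, so unstandardized coefficients are in outcome
units per predictor SD and the $\pm 1$ SD simple-slopes arithmetic is
exact.

## The moderated path model and simple slopes

The focused model regresses anxiety change on sex, minority status, BI,
baseline anxiety, the fusion dACC/PCC baseline and change scores, and the
four BI products.  Conditional slopes of a focal score at BI one SD below
the mean, at the mean, and one SD above are
$b_{\text{focal}} + m\,b_{\text{interaction}}$, with delta-method standard
errors from the observed-information coefficient covariance; the test
suite checks the SEs against a parametric bootstrap.  An optional extra
covariate (e.g. maternal education) can be added without changing the
interface.

## The synthetic cohort generator

The generator emulates the data structure the analysis assumes, not any
particular dataset:

* **Cohort**: 176 adolescents by default, 52.3% female, 24.4%
  racial/ethnic minority status (coded non-Hispanic White = 0, else 1).
* **Anxiety**: $(\eta_{13}, \Delta)$ bivariate normal in SCARED units.
  Defaults: mean change $-0.76$, change variance $14.30$, baseline
  variance 30 and covariance $-14.35$ (so the implied wave-2 latent
  variance is $\approx 15.6$, consistent with a standardized change of
  $\approx -0.19$), baseline mean 18 — chosen so that fewer than 1% of
  generated SCARED values hit the 0-82 bounds before rounding.  The
  diagnosis indicator is drawn from a logistic link on the latent with
  intercept $-2.2$ and slope $0.08$, giving a prevalence near 20%.
* **BI** is standard normal (z-scored), correlated 0.3 with baseline
  anxiety, consistent with probing slopes at $\pm 1$ SD.
* **Neural truths** per modality, region and wave are bivariate-normal
  (baseline, change) draws; fusion dACC defaults (baseline variance 0.16,
  change mean 0.17, change variance 0.07, covariance $-0.01$) imply the 0.37
  standardized change above.
* **Geometry**: a 48-mm box holds a Kuhn-subdivided tetrahedral mesh
  (6-mm spacing, 3072 elements) and a 3-mm voxel grid (16^3) with two
  disjoint box ROIs.  ROI signal is planted so that, at zero noise, the
  EEG, fMRI and fusion ROI means reproduce each subject's truths exactly
  (for fusion, the product of the EEG and fMRI truths) — the round-trip
  the tests assert.
* **Epochs**: response-locked trials at 250 Hz with a negative Gaussian
  deflection at 50 ms on the frontocentral cluster, amplitude scaled by
  the subject's wave-specific EEG dACC truth; correct trials carry noise
  only.
* **Missingness** is missing-at-random by construction: logistic models on
  the always-observed covariates (sex, minority status, BI) with a
  positive minority-status offset, acting at the *acquisition* level
  (~25% per modality and wave by default).  A fusion score is removed
  whenever either parent modality is, and a change score whenever either
  wave is, so fusion change scores are the most often missing — the
  qualitative pattern such cohorts show.  MNAR mechanisms are out of
  scope.

What the generator does **not** emulate: realistic head geometry or lead
fields, hemodynamic coupling, non-Gaussian symptom distributions, practice
or attrition effects correlated with unobserved severity.  Passing
recovery studies therefore demonstrate that the estimators are correct and
calibrated under the assumed structure — not that the substantive findings
would replicate in new cohorts.

## Recovery studies and problem sizes

`recovery_study()` repeats generate-and-refit cycles with replicate seeds
`base_seed + i`.  The package's standard studies use 200 replicates at the
default cohort size (n = 176), and 400 replicates for null-calibration of
the block test; these sizes put Monte-Carlo standard errors comfortably
below the decision tolerances while keeping a full run in the minutes
range on one core.

One estimator property is worth knowing when reading those outputs: the
ML/OLS estimate of a block's $\Delta R^2$ is the *sample* increment, which
is inflated by roughly $p_k(1 - R^2)/n_{\text{eff}}$ (here $p_k = 8$
predictors per neural block, with missingness further shrinking
$n_{\text{eff}}$).  Near-null blocks therefore average a few hundredths
above their generating contribution at this design size, and the terminal
block is correspondingly pulled down.  This is a property of the estimand
chosen by the blockwise design, not an implementation artifact — the OLS
oracle shows the identical behavior, and the recovery studies report it
rather than correct for it.

## Known limitations

* Robust (sandwich / Satorra-Bentler) corrections, WLSMV estimation for
  the categorical indicator, and Bayesian estimation are not implemented.
* The delta-method SE for $\gamma_k$ uses the complete-data Wishart
  covariance of the fitted moments; under heavy missingness it is an
  approximation (the block *test* does not rely on it).
* Factor scores are regression-method (empirical Bayes) scores; which
  estimator a given study used for "estimated change scores" is generally
  not stated, and shrinkage means score-level analyses are not identical
  to full-information joint models.
* The voxel-element tie rule (lowest element index) and centroid
  containment are documented conventions; other overlap definitions
  (partial volume, averaging across straddled elements) would give
  slightly different fusion scores at ROI boundaries.
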
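# fusionern

Multimodal (EEG-fMRI) measurement of error monitoring and the
longitudinal models that link it to adolescent anxiety.

## The problem

The error-related negativity (ERN) — a frontocentral negative EEG
deflection after error responses — is a candidate vulnerability marker for
anxiety, generated mainly by the dorsal anterior cingulate (dACC) and
posterior cingulate (PCC) cortices. EEG can isolate the response-locked
component but cannot separate these regions; fMRI can separate them but
cannot isolate the component. `fusionern` implements a multiplicative
fusion of the two — each fMRI error-contrast voxel is multiplied by the
current-density-reconstruction (CDR) difference value of the tetrahedral
source-model element containing it — and the statistical chain used to ask
whether such scores improve estimation of anxiety change from age 13 to
15, especially in youths with a history of behavioral inhibition (BI).

The package is aimed at quantitative researchers who want to study,
calibrate, or extend this analysis chain. Because cohort data of this kind
are restricted, a synthetic-cohort generator reproduces the study's
*structure* (latent anxiety change measured by parent/child SCARED and a
diagnostic indicator, planted ROI signals in all three modalities,
covariate-dependent missingness), so every stage runs end to end from a
seed.

## What is implemented

* **ERN waveforms** — baseline correction, condition ERPs, difference
  waves, and participant-specific peak selection (most negative
  frontocentral cluster mean in a post-response window).
* **Source fusion** — tetrahedral meshes with per-element CDR values,
  voxel-to-element mapping by barycentric containment, multiplicative
  fusion volumes, and dACC/PCC ROI means for EEG, fMRI, and fusion.
* **A FIML SEM engine** — mean-and-covariance structure models
  (`y = nu + Lambda eta + eps`, `eta = alpha + B eta + zeta`) with
  equality constraints, casewise (full-information) Gaussian likelihood
  over each subject's observed subvector, observed-information standard
  errors, standardization, ML fit indices, and regression factor scores.
* **Latent change score (LCS) models** — the two-wave anxiety LCS with
  cross-wave loading/intercept invariance
  (`eta15 = eta13 + Delta`; the mean and variance of `Delta` are the
  targets), and single-indicator neural LCS models with zero residual
  variances for each modality-by-region score pair.
* **Incremental validity** — sequential semipartial block contributions
  `gamma_k` (so `gamma_k^2 = delta-R^2_k`) of four predictor blocks
  (covariates; EEG; fMRI; fusion — each neural block with BI
  interactions), equal to hierarchical OLS increments on complete data;
  plus the focused moderated path model and simple slopes at BI ±1 SD.

## Worked example

```r
library(fusionern)
cfg <- generator_config()          # the study-scale defaults (n = 176)

## two-wave anxiety latent change, FIML over incomplete cases
gen    <- generate_cohort(cfg, seed = 1)
cohort <- apply_missingness(gen$cohort, NULL, cfg, seed = 1)$cohort
fit    <- fit_anxiety_lcs(cohort)
subset(fit$estimates, label %in% c("mean_delta", "var_delta"))
#>       label    est    se      z pvalue ci_lower ci_upper
#>   var_delta  8.492 5.027  1.689  0.091   -1.361   18.346
#>  mean_delta -0.942 0.477 -1.974  0.048   -1.878   -0.007
```

Mean latent change is in SCARED points (negative: slight average decline);
its variance is the individual-difference signal the downstream models try
to explain. One replicate at n = 176 scatters widely around the
generating values (-0.76 and 14.30); the replicated recovery studies
below average over 200 such cohorts.

```r
## blockwise incremental validity on a block-structured cohort
dat <- generate_block_cohort(cfg, seed = 1)
dat <- build_interaction_terms(dat,
         grep("^(eeg|fmri|fusion)_", names(dat), value = TRUE))
fit_incremental(build_block_model(), dat)
#> Blockwise incremental validity (FIML, n = 176)
#>    block n_predictors gamma delta_r2 cum_r2 statistic df1 df2   pvalue significant
#> 1 block1            4 0.775   0.6010  0.601     64.39   4 171 4.02e-33        TRUE
#> 2 block2            8 0.194   0.0375  0.639      2.12   8 163 3.71e-02        TRUE
#> 3 block3            8 0.181   0.0327  0.671      1.93   8 155 5.99e-02       FALSE
#> 4 block4            8 0.493   0.2435  0.915     52.47   8 147 2.46e-39        TRUE
```

The covariate block dominates, the single-modality blocks add little, and
the fusion block adds a large, significant increment — the pattern the
generator plants (population contributions 0.54 / 0.01 / 0.01 / 0.25).

```r
## moderated path model and simple slopes
pd <- generate_path_cohort(cfg, seed = 1)
pf <- fit_final_path(pd)
simple_slopes(pf, "fusion_dacc_13")
#>   level  slope   se      z   pvalue ci_lower ci_upper
#> 1    -1 -6.985 1.28 -5.452 4.99e-08    -9.50    -4.47
#> 2     0 -0.407 1.22 -0.333 7.39e-01    -2.80     1.99
#> 3     1  6.172 2.00  3.092 1.99e-03     2.26    10.08
```

The crossover: higher baseline dACC fusion activity goes with *rising*
anxiety in high-BI youths (+1 SD) and *falling* anxiety in low-BI youths
(-1 SD), with no association at mean BI. Slopes are SCARED points per SD
of the score.

A one-command end-to-end run (simulate → ERN peaks → fusion scores →
missingness → all model fits, with a written artifact manifest) is

```r
report <- run_pipeline(cfg, seed = 42, out_dir = "out/")
```

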
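# qeegprog

Quantitative EEG (qEEG) biomarkers and prognostic models for cognitive
decline in Parkinson's disease (PD).

Cognitive decline and dementia are common in the course of PD, and early
identification of patients at risk is a central problem of clinical
neurology. Resting-state EEG slowing — a shift of spectral power toward the
theta band — is one of the most promising prognostic markers. This package
implements, as a tested and reusable pipeline, a complete qEEG prognostic
analysis for a two-visit PD cohort:

1. **Automated EEG preprocessing** — zero-phase FIR band-pass (0.5–70 Hz)
   and 50 Hz notch filtering, robust bad-channel detection,
   spherical-spline interpolation (order *m* = 4), and fully automated
   blink removal by independent component analysis (kurtosis and
   frontal-topography criteria).
2. **Spectral biomarkers** — multitaper (DPSS) power spectral density;
   **global relative median power (GRMP)**: the channel-median spectrum
   integrated over delta (1–4 Hz), theta (4–8), alpha1 (8–10),
   alpha2 (10–13) and beta (13–30), normalised by total 1–30 Hz power so
   the five fractions sum to 1; and the **occipital median frequency**,
   the 50% quantile of the 4–14 Hz occipital spectrum.
3. **Cognitive scores** — a 14-test battery z-scored against a normative
   table (lower-is-better scores sign-flipped), grouped into six domains
   (attention, executive functions, fluency, long-term memory, working
   memory, visuospatial); the overall cognitive score (OCS) is the mean of
   all 14 z-scores. The outcome is the **change index of the OCS
   (CI-OCS)**: the paired follow-up minus baseline change divided by the
   standard error of the difference — a reliable-change-type statistic.
4. **Prognostic models** — univariate screening of baseline predictors
   (GRMP bands, median frequency, six domains, age, sex, education,
   disease duration, observation duration, LEDD, UPDRS-III), multivariate
   linear regression with backward elimination (α = 0.05), **exact LMG
   relative-importance decomposition** (shares sum to the model's
   explained variance, not to 100%), confounder checks against age, sex
   and education, ROC analysis against follow-up MMSE dichotomised at
   < 24, and random-forest importances (MDA, MDGC).

Because no patient-level data are distributed, a seed-deterministic
**synthetic-cohort generator** with planted effects stands in for the
clinical data: EEG recordings with known band composition, blinks and bad
channels, plus two-visit cognitive tables in which CI-OCS follows a known
linear model (default coefficients −3.16 for GRMP theta, 0.54 for the
executive domain, 0.19 for working memory). Every stage of the pipeline
therefore has a recoverable ground truth.

## Worked example

```r
library(qeegprog)

# synthetic cohort of 200 patients with the default planted model
feats  <- simulate_spectral_features(200, seed = 42)
cohort <- generate_cohort(cohort_gen_spec(n_subjects = 200, seed = 42), feats)

# z-score the battery, build domain scores and the CI-OCS outcome
prof <- cognitive_profiles(cohort$baseline, cohort$followup)

clinical <- cohort$baseline
clinical$observation_years <- cohort$followup$observation_months / 12
X <- build_predictors(feats, prof$baseline, clinical)

fit <- fit_prognosis(X, prof$change$ci_ocs,
                     mmse_followup = cohort$followup$mmse, seed = 1)
fit
#> <prognosis_fit> n = 200, alpha = 0.05
#>   final model (adj R^2 = 0.344, explained variance = 35.4%):
#>     grmp_theta             beta =   -3.697  p = 3.081e-06  LMG =   9.8%
#>     executive              beta =    0.562  p = 6.351e-13  LMG =  22.1%
#>     working_memory         beta =    0.184  p = 0.01878  LMG =   3.6%
#>   best ROC marker: executive (AUC = 76.2%, sens = 83%, spec = 60%)
```

The backward-eliminated model recovers the three planted predictors: a
higher baseline GRMP theta fraction predicts a more negative change index
(worse cognitive outcome; β̂ = −3.70 against a planted −3.16, inside its
95% CI), while better baseline executive and working-memory performance is
protective. The LMG column decomposes the model's explained variance
(35.4% of outcome variance) into per-predictor shares that sum to it;
`summary(fit)` additionally prints the univariate screen, the confounder
check and the random-forest importances, and `plot(fit)` draws the LMG bar
chart and the ROC curve.

The EEG path is exercised directly as well:

```r
rec <- generate_eeg(eeg_gen_spec(seed = 1))        # 64 ch, 250 Hz, 180 s
rec <- preprocess_eeg(rec, seed = 1)               # filter + interpolate + ICA
spectral_features(rec)                             # GRMP fractions + MF (Hz)
```

`run_pipeline(default_config(seed = 1))` orchestrates the whole chain and
writes `features.tsv`, `scores.tsv`, `model_report.json` (plus a readable
`model_report.txt` and `figures.pdf`) into a run directory; identical
config and seed reproduce the model report byte-for-byte.

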
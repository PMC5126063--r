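---
title: "Methods: qEEG biomarkers and prognostic modelling of cognitive decline in PD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qEEG biomarkers and prognostic modelling of cognitive decline in PD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and design decisions behind
`qeegprog` at the level of detail a methods-minded user needs to judge what
the package computes and what its validation does and does not show.

## The analysis in one paragraph

For a two-visit Parkinson's-disease cohort, baseline resting-state EEG is
cleaned fully automatically, summarised into global relative median power
(GRMP) per frequency band and an occipital median frequency; the cognitive
battery is z-scored against a normative table and aggregated into six domain
scores and an overall cognitive score (OCS); the outcome is the change index
of the OCS (CI-OCS), a standardised paired change. The modelling chain then
asks which baseline variables predict CI-OCS: univariate screening,
backward-elimination multiple regression, an exact LMG variance
decomposition of the final model, confounder checks, ROC analysis of the
retained markers against dichotomised follow-up MMSE, and random-forest
importances as a nonparametric cross-check.

## EEG preprocessing

**Filtering.** A linear-phase FIR filter (default order 2500) implements the
0.5–70 Hz band-pass with a 50 Hz notch, designed by frequency sampling and
applied forward–backward. Zero-phase application was chosen because group
delay would otherwise shift epochs and bias band-power estimates; the
achieved (two-pass) response at the default 250 Hz sampling rate is flat to
well under ±0.5 dB over 1–30 Hz with > 40 dB attenuation at 50 Hz and below
0.25 Hz. Edge transients are controlled by reflection padding.

**Bad channels.** A channel is flagged when its robust variance (squared
MAD) falls below 1e−3× or above 9× the cross-channel median, or when its
maximal absolute correlation with every other channel is below 0.1. These
thresholds are this package's own: the acquisition toolboxes used in
clinical practice do not publish their exact rules, and reproducible
automation matters more here than fidelity to an unpublished rule set. The
correlation criterion presumes volume-conducted dependence between channels,
which the synthetic generator therefore must (and does) produce.

**Interpolation.** Flagged channels are replaced by spherical-spline
estimates (order m = 4, ridge regularisation λ = 1e−5, 50 Legendre terms)
from the remaining good channels. Splines reproduce spatially constant
fields exactly; smooth fields interpolate with high fidelity, which the
tests verify on a synthetic dipolar topography.

**Blink removal.** The recording is decomposed by FastICA (symmetric
fixed-point iteration, tanh contrast) after PCA whitening to numerical
rank — the rank reduction also absorbs the degeneracy that interpolated
channels introduce. A component is removed when its activation kurtosis
exceeds 5 (Gaussian activations sit near 3), or when more than 60% of its
topography energy loads on the designated frontal channels *and* it is
clearly super-Gaussian (kurtosis > 4). The super-Gaussianity guard on the
frontal criterion prevents genuine frontal background components from being
removed; blink components are in practice caught by the kurtosis criterion
alone. With a fixed seed the decomposition is deterministic; rank-deficient
input degrades to a logged pass-through rather than an error.

**Ordering.** Interpolation precedes ICA. The reverse order is also
defensible; interpolating first means ICA sees a full-rank-reducible but
spatially complete montage, and the PCA step handles the induced rank
deficiency. This is flagged as a potential ordering difference from
clinical toolboxes.

## Spectral estimation and biomarkers

**Multitaper PSD.** 4 s epochs with 50% overlap; discrete prolate
spheroidal (Slepian) tapers computed from the standard tridiagonal
eigenproblem; eigenvalue-weighted averaging over tapers and epochs. The
default spectral half-bandwidth is W = 0.5 Hz, giving a time-half-bandwidth
product NW = 2 and K = 2NW − 1 = 3 tapers. (A wider W with three tapers is
internally inconsistent — the taper count was kept and W derived from it;
both are configurable.) The estimate is a one-sided density in µV²/Hz whose
integral equals the signal variance; the test suite checks this Parseval
property to 5% on white noise.

**GRMP.** The *global median spectrum* — the per-frequency median across
scalp channels (roles `active` and `occipital`; `bad` and `reference`
excluded) — is integrated over delta (1–4), theta (4–8), alpha1 (8–10),
alpha2 (10–13) and beta (13–30 Hz) and normalised by the 1–30 Hz total, so
the five fractions sum to 1. Two conventions are deliberately pinned down
because the name alone does not disambiguate them: (i) the median across
channels is taken *first*, then band powers are formed (the alternative —
per-channel relative power, then median — is available by computing
per-channel features); (ii) band edges are half-open `[low, high)`: a
10 Hz bin belongs to alpha2, not alpha1. The 1–30 Hz denominator is the
union of the five bands; a 0.5–70 Hz denominator can be obtained by passing
a custom `band_set()`.

**Occipital median frequency.** The median-across-occipital-channels
spectrum is restricted to 4–14 Hz and the frequency at which cumulative
power first reaches half the restricted total is returned, interpolating
linearly within the crossing bin. With 4 s epochs the grid step is 0.25 Hz,
so the flat-spectrum reference value 9.0 Hz is reproduced to within one bin.

A known estimator property: the W = 0.5 Hz taper bandwidth smears power
across band edges, biasing narrow bands (delta loses mass below the 1 Hz
denominator edge, alpha1 to both neighbours) by up to ~0.015 in absolute
fraction. The generator round-trip tolerance of ±0.03 accommodates this
leakage bias plus sampling variance; users comparing GRMP across pipelines
should hold W fixed.

## Cognitive scores and the outcome

Each of the 14 tests is z-scored against a normative mean and SD; tests
where lower raw scores are better (times, errors, omissions, the two
executive ratio scores) are sign-flipped at z-scoring so every aggregate is
higher-is-better. Domain scores are unweighted means of their member tests'
z-scores (3/3/2/2/2/2 tests across attention, executive, fluency, long-term
memory, working memory, visuospatial); the OCS is the unweighted mean of
all 14 z-scores — *not* the mean of the six domain means, which would
reweight small domains. "Divided attention: omissions" sits in working
memory, as the battery defines it, despite the name. Subjects with any
missing test are dropped and logged rather than imputed.

**CI-OCS.** The change index is the paired OCS change divided by the
standard error of the difference. The reliable-change literature offers
several estimators of that standard error; the package's default is the
cohort SD of the paired differences, which is computable from the data
alone and requires no external test–retest reliability. The Jacobson–Truax
`sqrt(2)·SEM` variant is available via the `reliability` argument when such
a coefficient exists. Under the default, CI-OCS has unit sample variance by
construction; it is antisymmetric under visit swap and invariant to adding
a constant to both visits.

## The modelling chain

* **Univariate screen.** One OLS fit per candidate predictor; predictors
  with slope p ≤ α = 0.05 are carried forward. No multiplicity correction
  is applied at this stage (a deliberate mirror of common clinical
  practice; a Benjamini–Hochberg option would be a one-line wrapper around
  `p.adjust` on the screen table).
* **Backward elimination** removes the largest partial-t p-value while any
  exceeds α. Exact ties are broken by dropping the alphabetically later
  name, making the result independent of column order. Numerically
  collinear inputs (condition number > 1e10) are an error naming the
  columns involved. Because the five GRMP fractions sum to one, a screened
  set containing all five (plus intercept) is exactly singular; the
  high-level `fit_prognosis()` therefore pre-drops the weakest screened
  members of any collinear subset before elimination and records them.
* **LMG decomposition.** Each retained predictor's share is the average
  over all predictor orderings of its sequential R² increment, computed
  exactly by subset enumeration with combinatorial weights (feasible up to
  12 predictors; the package refuses more rather than silently sampling).
  Shares are reported on the outcome-variance percentage scale — they sum
  to 100·R² of the model, not to 100 — so "explained variance" statements
  remain non-normalised. The test suite verifies the enumeration against a
  brute-force average over all orderings to 1e−10.
* **Confounder check.** For each retained predictor, its explained-variance
  share alone is compared with its LMG share after adding age, sex and
  education; a relative change below 20% is reported as "not confounded"
  (a reporting threshold, configurable).
* **ROC.** Markers are oriented so that higher values indicate impairment
  (GRMP delta/theta as-is; alpha bands, median frequency and cognitive
  scores negated), the positive class is follow-up MMSE < 24, AUC is the
  empirical (trapezoidal) area with the direction held fixed — so AUC is
  invariant under monotone transforms and AUC(m) + AUC(−m) = 1 — and the
  operating point maximises Youden's J, resolving exact ties toward higher
  specificity.
* **Random forest.** A 500-tree regression forest; MDA is the permutation
  importance (out-of-bag MSE increase, conventionally normalised by its
  standard error) and MDGC the total node-impurity decrease. For
  regression, "Gini" impurity is undefined; node-variance reduction is its
  standard regression analogue and is reported as MDGC in that spirit.
  Shapiro–Wilk normality statistics are computed for reporting only and
  never gate any step.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage has recoverable ground truth; its
defaults are fixed study conditions, not tuning knobs.

**EEG.** 64 channels on an upper-hemisphere Fibonacci lattice (vertex
reference, posterior occipital set, anterior tenth designated frontal),
250 Hz, 180 s. Each channel is a sum of brick-wall band-limited Gaussian
components whose variances equal the target band fractions exactly, which
makes the spectral target analytic. Within each band, 35% of every
channel's variance comes from four scalp-wide sources with smooth
affine-in-position gains — a minimal volume-conduction surrogate that gives
channels the mutual correlation real EEG has (without it, the
low-correlation bad-channel criterion would flag everything, and a blink
source would be linearly inseparable). Blinks are a rank-one train of
300 ms raised-cosine transients at 8× the background SD on the frontal
channels; bad channels are flat or high-variance. Background, blinks and
bad channels draw from separate seed streams, so configurations differing
only in artifact settings are sample-identical twins — the basis of the
artifact-removal tests. The default montage size matters: with too few
channels the frontal set carries too little information for *any* linear
unmixing to isolate a blink (the best achievable correlation with the true
blink source is information-limited), and 64 channels is the smallest
montage in this design that preserves the separability a 256-electrode
acquisition has. The generator does **not** emulate PD EEG microstructure
(spindles, asymmetries, nonstationarity), 1/f background is off by default
(available via `background_exponent`), muscle/ECG artifacts are absent, and
the recording duration default of 180 s is a package choice, not a quantity
taken from any acquisition protocol.

**Cohort.** Band fractions follow a logistic-normal model around typical
PD-cohort medians (delta/theta/alpha1/alpha2/beta ≈ 24/20/20/14/22% of
1–30 Hz power) with a latent "EEG slowing" factor loading positively on
delta/theta, negatively on alpha/beta and on the median frequency
(≈ 8.7 Hz). Domain scores share a latent cognition factor (inter-domain
correlation ≈ 0.35, typical of neuropsychological batteries) mildly and
negatively coupled to slowing. Per-test z-scores scatter around their
domain score with *zero within-domain mean*, so recomputed domain means
equal the planted ground truth exactly — without this, test-level noise
would attenuate the planted coefficients (errors-in-variables) and no
finite tolerance on coefficient recovery would be clean. The outcome is
planted directly: CI-OCS = 0.3 − 3.16·GRMPθ + 0.54·Exec + 0.19·WM + ε with
ε ~ N(0, 0.76²); the residual SD is calibrated once so the planted index
has approximately unit variance, consistent with its definition as a
standardised change score (the follow-up OCS is then reconstructed as
baseline + index × a 0.15-score change scale). Clinical covariates (age
67 ± 9 y truncated to [31, 84], male fraction 25/37, education 14 ± 3 y,
disease duration ~8 y, observation 37 ± 3 months, LEDD log-normal around
691 mg, UPDRS-III 14 ± 8, mood scales, baseline MMSE in [24, 30]) are
plausible for a PD cohort without claiming distributional fidelity;
follow-up MMSE declines with the planted index so that the ROC stage has a
meaningful dichotomy.

**What passing tests therefore show.** That the implementation recovers
known spectral compositions, planted regression structure and artifact-free
twins under Gaussian, linear, exactly-specified conditions — not that the
pipeline is robust to real-world violations (non-Gaussian EEG, nonlinear
outcome dependence, informative missingness, normative-table misfit).

## Validation problem sizes and a statistical caveat

The package's own validation runs use: 20 recordings (16 channels, 60 s)
for the spectral round trip; 180 s of white noise for Parseval; 50 random
3-predictor datasets for the LMG oracle; 100 replicates at n = 200 for
screen/elimination calibration; 50 replicates at n = 500 for end-to-end
recovery (feature-level simulation; the EEG-to-feature path is validated
separately by the round-trip tests); and 90 s twin recordings at the
64-channel default for blink removal. These sizes were chosen as the
smallest that make the corresponding property estimable with useful
precision.

One caveat deserves emphasis. With ~15 null candidate predictors, an
uncorrected α = 0.05 screen followed by backward elimination retains each
null with probability ≈ 3–5%, so the probability that the final model
contains *exactly* the three planted predictors and nothing else is bounded
near 0.95^15 ≈ 0.5–0.6 regardless of sample size; and even conditional on
exact support, the joint coverage of three marginal 95% confidence
intervals is at most ≈ 0.86. Exact-support-plus-coverage is therefore not a
property this (or any) α = 0.05 elimination pipeline can deliver in ≥ 90%
of replicates; the package's validation reports the exact-support rate, the
(much higher) contains-the-truth rate, and the recovered coefficient means
separately so that the two phenomena are not conflated.

## Numerical choices

DPSS tapers are cached per (epoch length, NW, K); concentration
eigenvalues come from the sinc-kernel quadratic form. The FIR filter is
applied via FFT convolution with the self-convolved impulse response
(exactly the forward–backward pass for a symmetric filter) after
reflection padding. FastICA runs at most 200 symmetric iterations to a
1e−7 convergence tolerance from a seeded random orthonormal start;
whitening retains eigenvalues above 1e−9 of the maximum. LMG subset R²
values use direct normal-equation solves on centred cross-products;
condition-number guards (1e10) protect elimination, LMG and the confounder
check, and error messages name the dependent columns. EDF export quantises
to 16 bits per channel at the channel's own physical range (relative error
≤ 1/32767 of the range).

## Known limitations

* No muscle/ECG artifact handling; the ICA criteria target blinks only.
* The normative table is synthetic; applying the scoring to real data
  requires supplying a real normative table via `generate_norms()`'s
  schema.
* LMG is exact-enumeration only (≤ 12 predictors) by design.
* `remove_blink_components()` removes whole components; partial
  (wavelet-thresholded) component cleaning is out of scope.
* The pipeline models a single cohort with complete cases; no mixed
  effects, survival extensions or external validation machinery.
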
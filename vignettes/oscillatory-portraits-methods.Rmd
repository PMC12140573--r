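---
title: "Methods: oscillatory portraits, effective connectivity, and their validation"
author: "oscportraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillatory portraits and effective connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, numerical choices and known
limitations behind `oscportraits`. Everything quantitative stated here is
computed by the test suite (`tests/testthat/`) or by
`scripts/acceptance.R`; nothing is asserted that the code does not verify.

## 1. Oscillatory elements and portraits

A trial's *portrait* is the 48-vector of mean log-normalized wavelet power
over every combination of region (IC1–IC4), movement epoch and frequency
band. Conventions, frozen across the whole package and its CSV interface:

* **Element order**: region-major, then epoch, then band
  (`IC1_Pre_theta`, `IC1_Pre_alpha`, …, `IC4_Post_gamma`); see
  `elementInfo()`.
* **Bands** (Hz, both edges inclusive): theta [4, 8], alpha [9, 12],
  beta [13, 35], gamma [36, 60]. The printed bands abut at integer
  boundaries; shared integer edges belong to the lower band.
* **Epochs** relative to movement onset/offset markers: Pre = [−1.5 s, 0),
  During = [onset, offset], Post = (offset, offset + 1.5 s].
* **Wavelets**: complex Morlet with ratio f0/σf = 7, frequency grid 2–60 Hz
  in 0.5-Hz steps. The grid is extended beyond the conventional 50 Hz
  ceiling so the gamma band is fully covered; this is our resolution of an
  ambiguity between the analysis grid and the band table, made once and
  applied everywhere.
* **Normalization**: no baseline interval exists in this paradigm, so raw
  power is log-transformed and, per subject, region and frequency, centred
  on the mean log power over *all* of that subject's trials and time
  points. The result is invariant to any global multiplicative rescaling of
  the raw signals.

Numerics: wavelets are truncated at ±3 temporal standard deviations,
normalized to unit energy, and applied by zero-padded FFT convolution; the
tests check agreement with direct time-domain convolution to 1e-10 and with
the analytic Gaussian spectral profile of the kernel (max relative shape
deviation < 5% where the response exceeds 1% of peak; the residual % error
is the truncation sidelobe). Samples within 3σt of the segment ends at the
lowest frequency are flagged as edge-affected but are *included* in epoch
means — by construction the epochs sit 1.5 s inside the analysed segment,
which is what the epoching itself provides, and no extra margin is added.
The full-table extractor (`portraitsFromSignals()`) streams two sufficient
statistics per (subject, region) instead of holding all time–frequency maps
in memory; the tests verify it is algebraically identical to
`normalizePower()` + `extractPortrait()`.

## 2. The shared estimation engine

All fitting goes through one model (`fitLMM()`): a Gaussian linear model
with a common intercept and slopes plus one random intercept per subject,
estimated by REML profiled over the variance ratio λ = τ²/σ². Because the
subject blocks make (I + λZZ′)⁻¹ available in closed form, the profiled
likelihood needs only X′X, X′y and per-subject sums — so the 48 targets of
one EC resample share a single crossproduct, and one EC run fits its ~2,400
models in seconds. The tests verify agreement with `lme4::lmer` (REML and
ML) to ~1e-6 for coefficients, variances and BLUPs, exact recovery on
noiseless data, and 95% Wald-CI coverage calibrated to within binomial
noise (empirically 95.3% over 400 replicates).

Choices and contracts:

* **REML by default**; ML available. At the simulated sizes the difference
  is far below test tolerances.
* **Predictors (and targets, in the connectivity modules) are z-scored with
  training statistics only.** The model is silent on units; without a
  common scale, "strong link", homophily sums and strength comparisons
  would be unit-dependent. A consequence verified by test: estimated EC is
  invariant to a common rescaling of all element columns.
* **Rank deficiency** (possible for bootstrapped 47-predictor designs)
  triggers a ridge penalty of 1e-6 with a warning, detected from the
  Cholesky pivots.
* **Unseen subjects** predict with u = 0 (population level).
* **Binary targets**: pairwise classification reuses the same Gaussian
  engine as a linear probability model on 0/1 labels; its continuous output
  is the ROC score (AUC is rank-based, so no calibration is needed).
* The behaviour-prediction "generalized linear models" are treated as this
  same Gaussian identity-link model; no family was specified and the
  evaluation metrics (Pearson r, MSE) are Gaussian-natural.

## 3. Connectivity

* **FC**: Pearson correlations over trials, averaged over 50 subsamples of
  75% of trials. `nBoot = 0` gives the deterministic all-trials matrix.
* **EC**: per target, the random-intercept regression on the other 47
  (optionally 49, adding `error` and `duration`) nodes; weights are
  coefficients averaged over 50 subsamples, orientation (target row, source
  column); per-target performance is Pearson r between held-out 25%
  predictions and observations, averaged over resamples (the spec of record
  for this package; pooling held-out predictions instead changes values by
  less than the resampling noise).
* **Resampling** is subsampling *without* replacement — "75% of the data"
  — keeping the held-out 25% disjoint; it is stratified by subject because
  a random intercept is unidentifiable for a subject absent from training.
* **Signs**: signed coefficients are stored; |w| is used wherever a
  nonnegative weight is required (thresholds, homophily, strengths), since
  ratios of signed sums are ill-behaved under cancellation.
* **Cross-training**: models fitted on category A's training trials are
  evaluated on every category B's held-out trials; the (A, B) entry is the
  mean Pearson r over the 48 targets, averaged over 10 (configurable)
  resamples.

## 4. Network statistics

Homophily ratios are weight fractions over same-label ordered pairs
(diagonal excluded), one per label axis. On the uniform complete graph they
equal the label-frequency baselines 528/2256 ≈ 0.234 (spatial, spectral)
and 720/2256 ≈ 0.319 (temporal) — the closed forms the tests pin down. The
permutation null shuffles *one* label axis across nodes at a time, keeping
the other two attached, so each axis's null isolates that axis; p-values
use the add-one convention (1 + #{null ≥ obs}) / (1 + n). Homophily is
computed on all weights (not only strong links): the defining ratios
reference total weight. Strong links are entries strictly above the 97th
percentile of |w| pooled over a set of networks, so an all-equal network
has none.

## 5. The synthetic generator: what it emulates, and what not

`generatePortraits()` draws portraits from
x = μ_c + u_s + A_c z + γ_c·err + η with A_c = B + δR_c. The defaults are
the package's frozen study conditions:

* 24 subjects, 600 trials per category (within the source paradigm's range
  of trials per subject), k = 5 latent factors;
* backbone B: one factor per region (loading 0.4 on its 12 elements) plus
  a global factor (0.2), with N(0, 0.1²) jitter to guarantee full column
  rank — this reproduces the dominant spatial/temporal homophily of real
  element networks;
* δ = 1 with orthonormal R_c: category manifolds differ by rotation, not
  scale;
* category means μ_c are unit vectors scaled by `category_separation = 1`,
  spreading ≈0.14 per element across all 48 — small enough that every
  per-element Bhattacharyya overlap stays ≥ 0.8, large enough that the
  joint portrait discriminates. This is a deliberate design choice: with
  *exactly* matched marginals and equal means, a linear classifier has
  population AUC 0.5 regardless of manifold rotation, so "heavily
  overlapping marginals yet discriminable portraits" — the phenomenon of
  interest — requires a distributed mean shift;
* τ = 0.5 subject-intercept sd, σ = 1 residual sd, error drive γ = 0.15/0.3
  into During/Post elements with error sd 1, Hit/Miss labels coupled to
  |err| < 1 by default; duration = 1 + v′x + N(0, 0.15²) with v = 0.05 on
  During elements, clipped at 0.4 s (clipping affects ≪1% of trials and
  keeps every signal long enough for the 2-Hz wavelet).

`groundTruthEC()` returns the population regression coefficients
−Ω_ts/Ω_tt from the closed-form covariance Σ_c = A_cA_c′ + error_sd²γγ′ +
σ²I. It deliberately *excludes* the subject-intercept term τ²I: the
random-intercept estimator absorbs per-subject offsets and converges to the
within-subject regression. With `standardized = TRUE` the truth is mapped
to the z-scored scale on which `fitEC()` reports.

Two frozen scenario configurations probe the direction of behaviour
coupling. `errorDriverConfig()` makes error a strong exogenous *driver*
(γ = 0.5 into 32 elements): its out-strength in the behaviour-augmented EC
exceeds its in-strength. `durationReadoutConfig()` makes duration a noisy
*readout*; the asymmetry (in > out) requires the readout to tap the shared
factor component — strong block loadings (0.8), modest residual (0.5) and
readout noise comparable to the readout signal (0.75). This is not a
tuning knob but a structural requirement: a near-noiseless readout of
individually-noisy elements genuinely becomes a useful *predictor* of each
element and the asymmetry reverses. Both asymmetries hold in 100/100
seeded replicates.

`generateSignals()` renders portraits as band-limited Gaussian noise whose
per-epoch amplitude is exp(element/2), with 50-ms cosine ramps at epoch
boundaries plus 1/f broadband noise. Gaussian band noise (rather than
sinusoids) matches the burst-like, non-phase-locked character of cortical
oscillations without modelling burst statistics. What the generator does
*not* emulate: trial-order dynamics (learning curves — trials are
exchangeable within category), volume conduction / ICA mixing, artifacts,
non-Gaussian heavy tails, and any phase coding. Passing tests therefore
demonstrate correctness of the estimators under the generative model, not
fidelity of any particular real dataset.

## 6. Surrogates

`iaaft()` implements the standard iterative amplitude adjusted Fourier
transform loop: from a random permutation, alternately impose the original
amplitude spectrum (keeping phases) and rank-remap onto the original's
sorted values; stop when the rank ordering stabilises, the relative RMS
spectral mismatch falls below tol, or at max_iter. The returned iterate is
the rank-remapped one, so the value multiset is *exactly* preserved (an
invariant the tests assert via `identical(sort(x), sort(s))`), while the
spectrum matches to <1e-2 relative RMS on AR(1) noise. Surrogates are
generated per trial and per region. Because IAAFT spreads each trial's band
power uniformly over the trial, it abolishes epoch-specific structure: on
the cross-epoch coupling scenario, the coupled pairs lose >50% of their EC
weight (measured ≈84%).

## 7. Protocols, sizes and tolerances

Fixed protocol numbers follow the source protocols: 50 bootstrap resamples
at 75% for FC/EC, 100 stratified splits for pairwise discrimination, 20
folds at 75% for behaviour prediction, 1,000 label shuffles for homophily
nulls, 97th percentile strong links, 20 equal-width histogram bins over the
pooled range for Bhattacharyya overlaps (bin count reported with the
result). Stratified splits for classification preserve the category ×
subject mix; behaviour folds are random 75/25 splits stratified by subject.
Label/target shuffles permute the *training* portion only.

Problem sizes used by the validation runs (chosen to finish in minutes on
one CPU while leaving wide margins): EC recovery at 5,000 trials × 8
subjects (estimate–truth correlation ≈ 0.91 against the ≥ 0.8 bar);
cross-training at 600 trials per category; behaviour-node asymmetries at
150 trials per category × 100 replicates; time–frequency validation on 200
rendered trials (element recovery min r ≈ 0.82 against the > 0.7 bar). The
acceptance script reruns all of these from scratch from a single `--seed`.

## 8. Known limitations

* EC is cross-trial and regression-based: directed in the predictive sense,
  not causal, and blind to within-trial lags (no Granger-style analysis).
* The linear engine cannot represent purely covariance-borne category
  differences; this is a property of the model class, inherited by design.
* Classification is strictly pairwise; no 6-way classifier is provided.
* Coefficients of the 48-predictor models are collinearity-degenerate
  individually; they are exported but should be interpreted only in
  aggregate (weights, strengths, homophily).
* The per-subject normalization assumes enough trials per subject for a
  stable mean log-power reference; single-digit trial counts per subject
  make portraits noisy.
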
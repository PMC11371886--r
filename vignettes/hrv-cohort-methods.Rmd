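---
title: "Methods: heart rate variability markers, reference ranges and survival modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart rate variability markers, reference ranges and survival modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hrvcohort` implements a complete analysis path for cohort studies of heart
rate variability (HRV) from ambulatory (Holter) electrocardiography: from raw
RR-interval recordings to twenty HRV markers, percentile reference ranges from
a healthy subgroup, data-driven marker selection by a random survival forest,
and standardized association and survival models. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices, and
the limitations a user should know about. Every empirical statement here is
recomputed by the package's test suite or by `scripts/acceptance.R`; the
vignette itself reports no numbers those checks do not produce.

## From RR intervals to NN series

A Holter recording arrives as a sequence of RR intervals (milliseconds). Two
text dialects are read by `read_rr_text()`: one interval per line, or a
two-column CSV of beat time and interval. Beat timestamps, when absent, are
reconstructed as cumulative sums; all timestamps are elapsed seconds from the
start of the recording — no wall-clock semantics are needed because every
downstream window (SDANN segments, spectral windows) is defined on elapsed
time.

**Eligibility.** `check_eligibility()` excludes recordings with pacemaker
stimulation, with atrial fibrillation during at least half of the wearing
time, or from heart-transplant recipients. The AF fraction is metadata
supplied with the recording (annotation software produces it in practice);
detecting AF from intervals is out of scope.

**Artifact filtering.** Clinical systems filter artifacts but rarely document
how. `filter_to_nn()` uses a conventional three-rule sequential filter, all
parameters exposed via `filter_params()`:

* absolute bounds: intervals outside 300–2000 ms are rejected;
* annotation: beats labelled ectopic/artifact/AF are rejected;
* relative rule: a beat deviating from the running median of the last 11
  *accepted* intervals by more than 20% of that median is rejected.

The reference window is trailing rather than centred so the filter is causal
and provably idempotent: a filtered series passes unchanged through a second
application (the accepted prefix determines the same running medians). The
20% / 11-beat defaults mirror common Holter practice (the RHRV family of
filters); they are a stated convention, not a reconstruction of any
particular device's rule. Accepted beats keep their original timestamps, so
rejections leave gaps in elapsed time instead of shifting later beats.

**Tachogram.** Spectral analysis needs uniform sampling. `resample_tachogram()`
interpolates interval-versus-time onto a 4 Hz grid (the HRV convention).
Cubic-spline interpolation is the default: linear interpolation between beats
~0.8 s apart acts as a low-pass filter that attenuates the respiratory (HF,
0.15–0.40 Hz) band noticeably more than the LF band, inflating LF/HF by tens
of percent on realistic signals. The spectral-fidelity check in the
acceptance suite (LF:HF recovering the generator's squared amplitude ratio
within 15% on 22 h records) fails with linear interpolation and passes with
the spline; linear remains selectable.

## The twenty markers

### Time domain

`time_domain_markers()` computes mean HR, SDNN, SDANN, rMSSD and pNN50.
Conventions, each of which has a second defensible variant:

* mean HR is `60000 / mean(NN)` — the rate of the mean interval, not the mean
  of instantaneous rates (the two differ by Jensen's inequality; the choice
  is configurable in spirit by computing from the table directly);
* all standard deviations use the sample (n−1) denominator;
* pNN50 counts differences *strictly* greater than 50 ms, following the
  definition "differ by more than 50 ms";
* SDANN segments are contiguous 300 s windows of elapsed time anchored at the
  first accepted beat; a segment whose accepted intervals cover less than
  half of it (gaps from rejected beats) is dropped rather than treated as a
  short segment, and SDANN is reported missing — never 0 — when fewer than
  two valid segments remain.

### Frequency domain

`band_powers()` estimates the power spectral density of the linearly
detrended tachogram by Welch's method (5-minute Hann segments, 50% overlap)
and integrates it over four bands. Band edges default to the long-standing
Task Force conventions, anchored by the definition of ULF as oscillations
with periods of at least 5 minutes: ULF (0, 1/300], VLF (1/300, 0.04],
LF (0.04, 0.15], HF (0.15, 0.40] Hz. Bin membership is lower-exclusive /
upper-inclusive, so the four bands partition (0, 0.40] and their powers sum
exactly to the total. Powers are in ms² (PSD integrated over Hz); published
tables sometimes label these "ms/Hz", which we treat as a label of the same
quantity since integration over a band cancels the /Hz. A band the recording
cannot resolve is reported missing, and LF/HF is missing (not infinite) when
HF power is zero.

Two time-resolved ULF summaries complement the static ULF power:

* `stft_band_series()` slides a long window (default 1800 s, step 300 s; a
  5-minute window cannot resolve periods ≥ 5 min) and integrates a detrended
  Hann periodogram over the band per window. The marker `ulf_fourier` is the
  interquartile range (Q3 − Q1) of this track — a dispersion measure of how
  ULF power moves over the day.
* `wavelet_band_series()` computes a maximal-overlap discrete wavelet
  transform (MODWT, least-asymmetric 8-tap filters, circular boundary) of
  the detrended tachogram and sums squared detail coefficients over the
  levels whose dyadic bands (fs/2^(j+1), fs/2^j] intersect ULF — at 4 Hz,
  levels 10 and deeper. The marker `ulf_wavelet` is the median of this
  track. Oscillations slower than the deepest level the recording length
  supports fall into the smooth and are excluded. The MODWT is implemented
  in-package (pyramid algorithm) and is verified against a direct
  convolution with the equivalent level filters.

### Non-linear indices

All non-linear markers are computed on the beat-domain NN sequence, not the
resampled tachogram, to preserve beat-to-beat dynamics. Parameters live in
`nonlinear_params()`.

* **Acceleration / deceleration capacity** (`prsa_capacity()`):
  phase-rectified signal averaging. Anchors are beats that lengthen
  (deceleration) or shorten (acceleration) the interval, excluding changes
  above 5% of the preceding interval (the customary ectopy guard). The
  capacity is the Haar-like contrast (X(0) + X(1) − X(−1) − X(−2)) / 4 of
  the anchor-aligned mean profile. On a +2 ms/beat ramp DC is exactly 2 ms,
  which the acceptance suite asserts identically.
* **Time lag** (`time_lag()`): the smallest shift at which the sample
  autocorrelation falls below 1/e. First-zero and first-minimum criteria are
  selectable; saturation at `max_lag` (default 50) is flagged rather than
  silently returned.
* **Embedding dimension** (`embedding_dimension()`): Cao's method. E1(d) is
  computed up to `max_dim` + 1 and the smallest d with E1(d) ≥ 0.95 and
  |E1(d+1) − E1(d)| < 0.05 is returned; stochastic series that never
  saturate return `max_dim` with a flag. Nearest neighbours use a Chebyshev
  metric with an evenly spaced reference subset (default 1000 points) to
  bound the O(n²) cost.
* **Correlation (fractal) dimension** (`correlation_dimension()`):
  Grassberger–Procaccia. Correlation sums with Theiler exclusion (default:
  the time lag) over log-spaced radii chosen from the empirical distance
  distribution; the dimension is the least-squares slope of log C(r) versus
  log r over the scaling region, by default radii with C(r) in
  [5·10⁻⁴, 0.2] — away from both the discreteness floor and saturation.
* **Sample entropy** (`sample_entropy()`): SampEn(m = 2, r = 0.2·SD),
  Chebyshev distance, self-matches excluded, −ln(A/B). Both the A = 0 and
  the zero-variance paths are explicit missing/error outcomes.
* **Maximal Lyapunov exponent** (`max_lyapunov()`): Rosenstein's method with
  a neighbourhood radius of 100 ms — the radius the marker is conventionally
  subscripted with in the cohort literature — a Theiler window equal to the
  time lag, and a divergence-slope fit over iterations 1–10. If more than
  90% of points have no neighbour within the radius the marker is missing
  with a diagnostic.

Every "cannot compute" outcome across the marker set is an explicit missing
value carrying a reason code (collected per record by `compute_markers()`),
never a silent zero. The O(n²) estimators cap the series at `max_points`
(default 10 000 beats) — on a 24 h recording this analyses roughly the first
2¼ hours for those markers, a compute/precision trade-off the user can move.

Published cohort tables report non-integer medians for the embedding
dimension even though any single estimate is an integer; this suggests
averaging over segments or a different estimator. We return the
integer-valued Cao estimate and do not imitate the unexplained averaging.

## Reference ranges and summaries

The reference group is defined by `healthy_mask()`: heart-failure stage 0/A,
excluding long-standing (≥ 10 y) diabetes without dietary treatment and
degenerative/structural neurological disorders. `derive_reference_range()`
takes the 5th and 95th percentiles of each marker in this group, with a
configurable floor (default 20 non-missing values) below which it refuses.
All quantiles use linear interpolation at position p(n−1) between order
statistics (R's type 7), and the convention is recorded in the output
metadata because percentile conventions differ across software at small n.
Classification is bound-inclusive: a value equal to a bound is inside, since
published out-of-range counts are strictly "< 5th" and "> 95th" percentile.
Tertile groups are lowest ≤ t1 < middle ≤ t2 < highest, matching the cut
descriptions used for cumulative-incidence stratification.

## Marker selection

Two rankings are combined by `select_top_union()` (top 10 of each, union,
sources recorded):

1. **Literature**: hit counts per marker arrive as a CSV (`rank_by_hits()`);
   the search itself is not executed because web hit counts are neither
   stable nor reproducible. Ties break lexicographically.
2. **Survival forest**: `fit_survival_forest()` grows bootstrap log-rank
   trees. At each node, `mtry` (default ⌈√p⌉) markers are sampled and age
   and sex are *forced* into the candidate set — this is how "adjusted for
   age and sex" is realized in a forest. Candidate cut points are the
   node-level quantiles at 10 evenly spaced probabilities, which bounds
   compute and makes the forest reproducible from a seed; the split
   maximizing the absolute two-sample log-rank statistic wins. Splitting
   stops below 15 samples or 3 events. `minimal_depth_importance()` scores
   each variable by the depth of its shallowest split per tree, assigning
   variables never split in a tree that tree's maximal terminal depth (the
   harshest defensible penalty for absence; recorded in metadata), and
   averages over trees.

Because splits depend on predictor order only, the forest's topology and
depth ranking are invariant under strictly monotone transforms of any
predictor (the suite asserts exact equality of structures after an `exp`
transform). The log-rank split statistic is verified against the textbook
risk-table formula to 10⁻¹⁰.

## Outcome models

`standardize_columns()` divides by the sample SD without centering — the
literal "divided by their standard deviations" — which is inconsequential for
Cox models and for slopes in linear models. The SD used for per-SD hazard
ratios is taken from the modelled (heart-failure) sample and is returned for
back-transformation.

`cox_fit()` maximizes the Breslow partial likelihood by Newton–Raphson
(score-norm tolerance 10⁻⁹, ≤ 50 iterations), with Efron ties behind a flag.
Breslow is the default because it is the simplest exactly specifiable
convention and is what the brute-force likelihood oracle in the test suite
implements. Monotone likelihood (separation) is flagged via
`converged = FALSE` when any coefficient passes |β| > 20 or the score becomes
non-finite. Fits agree with `survival::coxph` to 10⁻⁷ in both tie modes (a
cross-check only; the implementation is independent). A three-subject toy
problem with a closed-form root, β = −½ ln 2, is asserted to 10⁻⁷.

`run_model_battery()` fits one standardized Cox model per marker per
adjustment tier (`age_sex`, or `full` with user-named risk-factor,
comorbidity and medication columns — cohort covariate sets are
study-specific, so the full tier is configuration, not code). A binary
"outside the reference range" predictor variant is available. Markers
missing for more than half the subjects are skipped with a warning.
`linear_fit()` provides the complementary linear battery (standardized
marker on clinical profile) and `cumulative_incidence()` the per-group
1 − Kaplan–Meier curves (via `survival::survfit`, checked against hand
product-limit arithmetic).

One statistical subtlety the acceptance design respects: hazard ratios are
non-collapsible, so a per-SD effect configured in the generator is only the
estimand of a battery fit when it is the sole marker effect in that cohort.
Recovery checks therefore simulate one configured effect per cohort.

## The synthetic-data module

No public Holter cohort accompanies this implementation, so
`gen_rr_record()` and `gen_cohort()` generate data with known ground truth.
The RR generator is additive in the beat domain:

NN(t) = mean_nn + a_lf · sin(2π f_lf t) + a_hf · sin(2π f_hf t)
        + a_circ · cos(2π t / 86400) + AR(1) noise,

evaluated at the accumulating beat times, with ectopic events injected as
(0.6×, 1.4×) interval pairs and artifacts as spurious 100–250 ms intervals.
Defaults: 22.49 h duration (a typical cohort mean wearing time), 800 ms mean
interval, LF 25 ms at 0.1 Hz, HF 15 ms at 0.25 Hz, circadian 150 ms, AR(1)
coefficient 0.85 with 15 ms innovations, ectopy rate 0.002, artifact rate
0.0005 — chosen once so that SDNN, pNN50 and band powers land in
physiologically plausible ranges for an adult cohort, and kept fixed.
The additive beat-domain form was chosen over an integral-pulse-frequency
model for analytic tractability: expected band powers are A²/2 per tone, so
spectral recovery is checkable in closed form. What the generator does *not*
emulate: respiratory coupling, QRS morphology, true multifractality of sinus
rhythm, non-stationary activity bouts. Passing tests therefore demonstrate
correctness of the estimators on signals with known structure, not clinical
validity on real Holter data.

`gen_cohort()` draws covariates (age ~ N(64.5, 10.5²), 35.4% female),
standard-normal marker z-scores (optionally mean-shifted in the
heart-failure group to emulate depressed HRV), and survival times from a
Weibull proportional-hazards model (shape 1.2, scale 40 years baseline,
administrative censoring at 8 years; roughly a 12–15% event rate at the
defaults, matching a heart-failure cohort over that horizon). Two modes:

* `"markers"` — z-scores are the ground truth directly; this is what the
  parameter-recovery and coverage checks use (n = 1500 with 100 replicates
  is computable in seconds);
* `"signal"` — each subject also receives an RR recording whose LF/HF
  amplitudes are scaled by the subject's z-score, so the full pipeline can
  run end to end on the bundle; ground truth is emitted as versioned JSON by
  `write_cohort()` so checks never re-derive it from the pipeline under
  test.

## Problem sizes used by the checks

The test suite and acceptance script run at deliberately desk-scale sizes,
stated here as the package's own choices: oracle-equivalence checks at
n ≤ 500 beats; chaotic-map fixtures at n = 10⁴ (Lyapunov, correlation
dimension) and n = 5000 (Cao); one 22.49 h generated recording for spectral
fidelity; reference-range self-consistency at n = 500; Cox coverage at
n = 1500 × 100 replicates per set-point (hazard ratios 1.53 and 0.70 per SD);
forest selection at n = 300, 200 trees, 20 seeds. End-to-end pipeline tests
use 50 subjects with 15-minute recordings — markers that need longer records
(ULF summaries) are then reported missing with reasons, which is itself part
of the tested contract.

## Known limitations

* The artifact filter is a stated convention; against recordings filtered by
  a specific clinical system, small disagreements in accepted beats are
  expected.
* ULF power from 5-minute Welch segments rests on a single Fourier bin; the
  STFT and wavelet ULF summaries are the better-resolved ULF quantities.
* The wavelet track uses circular boundary handling; for strongly trended
  recordings the first/last equivalent-filter widths of each level carry
  wrap-around energy (the linear detrend mitigates most of it).
* Cao's embedding dimension degenerates on series with exactly duplicated
  values (zero nearest-neighbour distances are skipped); heavily quantized
  interval series may need dithering.
* The survival forest is a ranking device (minimal depth); it does not
  provide calibrated survival predictions, permutation importance or
  proximity analysis.
* Competing-risks analyses (e.g. cause-specific cardiac death against other
  deaths) are supported only as cause-specific Cox fits, not Fine–Gray
  models.
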
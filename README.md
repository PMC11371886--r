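# hrvcohort

Heart rate variability (HRV) — the beat-to-beat variation of the
normal-to-normal (NN) interval — reflects autonomic control of the heart and
is depressed in heart failure. `hrvcohort` is an R package for cohort
studies that work from 24 h ambulatory (Holter) RR-interval recordings. It
covers the full analysis path:

1. **Preprocessing** — read plain-text RR recordings, apply eligibility
   rules (pacemaker, atrial fibrillation ≥ half the recording, heart
   transplant), filter artifacts with a running-median rule, and resample
   the NN series to a uniform 4 Hz tachogram.
2. **Twenty HRV markers** —
   *time domain*: mean HR, SDNN, SDANN, rMSSD, pNN50;
   *frequency domain*: ULF/VLF/LF/HF band powers by Welch's method, LF/HF,
   total power, plus two time-resolved ULF summaries (IQR of the ULF
   short-time Fourier track, median of the ULF wavelet track via an
   in-package MODWT);
   *non-linear indices*: acceleration and deceleration capacity (AC, DC) by
   phase-rectified signal averaging, time lag (autocorrelation decay below
   1/e), embedding dimension (Cao), correlation dimension
   (Grassberger–Procaccia), sample entropy, and the maximal Lyapunov
   exponent (Rosenstein, 100 ms radius).
3. **Reference ranges** — 5th/95th percentile bounds per marker from a
   healthy/at-risk subgroup, bound-inclusive classification, tertiles, and
   cohort-table summaries.
4. **Marker selection** — literature hit-count ranking combined with
   minimal-depth importance from a random survival forest with log-rank
   splitting (age and sex forced into every candidate set).
5. **Outcome models** — per-SD standardized Cox proportional-hazards
   batteries (own Breslow/Efron Newton–Raphson implementation), linear
   model batteries, and cumulative-incidence (1 − Kaplan–Meier) curves.
6. **Synthetic data** — a generator for 24 h Holter-like NN series
   (LF/HF sinusoidal modulation, circadian ULF drift, AR(1) beat noise,
   ectopy and artifacts) and for cohorts whose survival times follow a
   Weibull proportional-hazards model with configurable per-SD log-hazards,
   so every stage is testable with known ground truth.

The key modelled quantity downstream is the per-SD hazard ratio
`HR = exp(β·SD(x))` from a Cox model `λ(t | x) = λ₀(t) exp(βx)` with the
marker divided by its sample standard deviation, reported with Wald 95%
confidence intervals.

## Worked example

```r
library(hrvcohort)

## a synthetic 2 h recording, filtered to NN intervals
rr <- gen_rr_record(rr_gen_params(duration_h = 2, seed = 42))
nn <- filter_to_nn(rr)
nn
#> <nn_series 'synthetic': 7611 NN beats (37 rejected), 2.00 h>

round(unlist(time_domain_markers(nn)), 2)
#> mean_hr    sdnn   sdann   rmssd   pnn50
#>   63.72   36.11    8.06   23.78    3.04

tg <- resample_tachogram(nn)          # 4 Hz cubic-spline tachogram
round(unlist(band_powers(tg)), 1)
#>         ulf         vlf          lf          hf total_power       lf_hf
#>        56.3       428.4       541.8       177.3      1203.8         3.1

pr <- prsa_capacity(nn, "deceleration")
sprintf("DC = %.2f ms over %d anchors", pr$capacity, pr$profile$anchor_count)
#> "DC = 10.12 ms over 3605 anchors"
```

The mean heart rate is 63.7 beats/min (the 2 h window starts at the
circadian maximum of the generator, hence longer-than-average intervals);
SDNN of 36 ms over 2 h, an LF/HF ratio of 3.1 and a deceleration capacity of
10 ms describe a variable, vagally responsive rhythm. On a cohort, the same
markers feed reference ranges and survival models:

```r
co <- gen_cohort(cohort_gen_params(800, betas = c(ac = log(1.53)), seed = 1))
derive_reference_range(co$markers, co$covariates$group == "healthy", "ac")
#> <reference_range ac: [-1.44545, 1.47218] (p 0.05/0.95, n = 225)>

cohort <- co$covariates; cohort$time <- cohort$time_years
run_model_battery(co$markers, cohort, adjustment_set("age_sex"),
                  time_col = "time", event_col = "event")
#>   marker   hr   lo  hi        p   n events
#> 1     ac 1.41 1.17 1.7 0.000255 800    116
```

The battery recovers a hazard ratio of 1.41 per SD of acceleration capacity
(95% CI 1.17–1.70) against the configured generating value of 1.53 — inside
its own confidence interval, as the coverage checks below verify
systematically.

`run_pipeline(config)` (or the thin wrapper `inst/scripts/hrvcohort.R` with
verbs `simulate`, `preprocess`, `run-all`) executes the whole chain from a
directory of RR files plus metadata/covariate CSVs to a bundle of artifact
CSVs/JSONs: eligibility decisions, the 20-marker table with missing-value
reason codes, reference ranges, a cohort summary table, the forest +
literature selection report, tertile cumulative-incidence curves and both
model batteries, with the effective configuration and seed echoed alongside.

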
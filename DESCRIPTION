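Package: hrvcohort
Title: Heart Rate Variability Markers, Reference Ranges and Survival Modelling
    for Holter Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline from raw RR-interval recordings to
    cohort-level survival analysis of heart rate variability (HRV). Reads
    plain-text RR recordings, applies eligibility rules and artifact
    filtering to obtain normal-to-normal (NN) interval series, and computes
    twenty HRV markers across the time domain (mean HR, SDNN, SDANN, rMSSD,
    pNN50), the frequency domain (ULF/VLF/LF/HF band powers, LF/HF ratio,
    total power, short-time-Fourier and wavelet ULF summaries) and
    non-linear indices (acceleration and deceleration capacity via
    phase-rectified signal averaging, time lag, embedding dimension,
    correlation dimension, sample entropy, maximal Lyapunov exponent).
    Derives percentile-based reference ranges from a healthy subgroup,
    ranks markers by literature hit counts and by minimal-depth importance
    from a random survival forest with log-rank splitting, and fits
    standardized Cox proportional-hazards and linear model batteries.
    Includes a synthetic-data module generating 24 h Holter-like NN series
    and cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
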
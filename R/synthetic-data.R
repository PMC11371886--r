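#' Parameters for the synthetic RR-record generator
#'
#' The generator emulates the signal structure the HRV markers assume in a
#' long ambulatory (Holter) recording: a mean interval with additive
#' low-frequency (Mayer-wave range) and high-frequency (respiratory range)
#' sinusoidal modulation, a 24 h circadian cosine supplying ultra-low
#' frequency power, AR(1) beat-to-beat noise, and sporadic ectopic beats
#' (premature/compensatory interval pairs) and short spurious artifact
#' intervals. The default wearing time is 22.49 h, a typical cohort mean.
#'
#' @param duration_h recording duration in hours (default 22.49).
#' @param mean_nn mean NN interval in ms (default 800, i.e. 75 bpm).
#' @param a_lf,f_lf LF modulation amplitude (ms) and frequency (Hz; default
#'   0.1 Hz).
#' @param a_hf,f_hf HF modulation amplitude (ms) and frequency (Hz; default
#'   0.25 Hz).
#' @param a_circ circadian (24 h cosine) amplitude in ms, the ULF driver.
#' @param ar_coef,ar_sigma AR(1) beat-noise coefficient and innovation SD
#'   (ms).
#' @param ectopy_rate per-beat probability of an ectopic event (a 0.6x /
#'   1.4x interval pair).
#' @param artifact_rate per-beat probability of a spurious short (< 300 ms)
#'   interval.
#' @param seed RNG seed (`NULL` = current RNG state).
#' @return object of class `rr_gen_params`.
#' @export
rr_gen_params <- function(duration_h = 22.49, mean_nn = 800, a_lf = 25,
                          f_lf = 0.1, a_hf = 15, f_hf = 0.25, a_circ = 150,
                          ar_coef = 0.85, ar_sigma = 15, ectopy_rate = 0.002,
                          artifact_rate = 0.0005, seed = NULL) {
  amps <- a_lf + a_hf + a_circ
  if (mean_nn <= amps)
    stop("mean_nn must exceed the summed modulation amplitudes ",
         "(intervals must stay positive)", call. = FALSE)
  if (ectopy_rate < 0 || ectopy_rate >= 1 || artifact_rate < 0 ||
      artifact_rate >= 1)
    stop("rates must lie in [0, 1)", call. = FALSE)
  stopifnot(duration_h > 0, abs(ar_coef) < 1, ar_sigma >= 0)
  structure(list(duration_h = duration_h, mean_nn = mean_nn, a_lf = a_lf,
                 f_lf = f_lf, a_hf = a_hf, f_hf = f_hf, a_circ = a_circ,
                 ar_coef = ar_coef, ar_sigma = ar_sigma,
                 ectopy_rate = ectopy_rate, artifact_rate = artifact_rate,
                 seed = seed),
            class = "rr_gen_params")
}

#' Generate one synthetic RR recording
#'
#' Beat times are built iteratively: the k-th interval is
#' `mean_nn + a_lf sin(2 pi f_lf t_k) + a_hf sin(2 pi f_hf t_k) +
#' a_circ cos(2 pi t_k / 86400) + AR(1) noise`, evaluated at the current
#' elapsed time `t_k`. Ectopic events replace an interval pair by
#' (0.6x, 1.4x) of the local value (labels `ectopic`); artifacts insert a
#' spurious 100-250 ms interval (label `artifact`). Deterministic for a
#' given seed.
#'
#' @param p an [rr_gen_params].
#' @param record_id identifier for the generated series.
#' @return an [rr_series] with labels.
#' @export
gen_rr_record <- function(p = rr_gen_params(), record_id = "synthetic") {
  stopifnot(inherits(p, "rr_gen_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  dur_s <- p$duration_h * 3600
  n_max <- ceiling(dur_s / (p$mean_nn - p$a_lf - p$a_hf - p$a_circ) * 1000) +
    10L
  noise <- if (p$ar_sigma > 0) {
    as.numeric(stats::arima.sim(list(ar = p$ar_coef), n_max,
                                sd = p$ar_sigma))
  } else numeric(n_max)
  nn <- numeric(n_max)
  t <- 0
  k <- 0L
  while (t < dur_s && k < n_max) {
    k <- k + 1L
    v <- p$mean_nn + p$a_lf * sin(2 * pi * p$f_lf * t) +
      p$a_hf * sin(2 * pi * p$f_hf * t) +
      p$a_circ * cos(2 * pi * t / 86400) + noise[k]
    v <- max(v, 1)
    nn[k] <- v
    t <- t + v / 1000
  }
  nn <- nn[seq_len(k)]
  labels <- rep("normal", k)
  # ectopic events: premature + compensatory pair replacing beats (j, j+1)
  if (p$ectopy_rate > 0) {
    ev <- which(stats::runif(k) < p$ectopy_rate)
    ev <- ev[ev < k - 1L & ev > 1L]
    ev <- ev[!duplicated(ev %/% 2L)]  # keep events apart
    for (j in ev) {
      base <- nn[j]
      nn[j] <- 0.6 * base
      nn[j + 1L] <- 1.4 * base
      labels[j] <- "ectopic"
      labels[j + 1L] <- "ectopic"
    }
  }
  # spurious short artifact intervals inserted into the sequence
  if (p$artifact_rate > 0) {
    at <- which(stats::runif(length(nn)) < p$artifact_rate)
    if (length(at)) {
      art_len <- stats::runif(length(at), 100, 250)
      keep_nn <- vector("list", length(nn))
      out_nn <- numeric(0); out_lab <- character(0)
      prev <- 0L
      for (ix in seq_along(at)) {
        j <- at[ix]
        out_nn <- c(out_nn, nn[(prev + 1L):j], art_len[ix])
        out_lab <- c(out_lab, labels[(prev + 1L):j], "artifact")
        prev <- j
      }
      if (prev < length(nn)) {
        out_nn <- c(out_nn, nn[(prev + 1L):length(nn)])
        out_lab <- c(out_lab, labels[(prev + 1L):length(nn)])
      }
      nn <- out_nn; labels <- out_lab
    }
  }
  rr_series(nn, record_id = record_id, labels = labels)
}

#' Generate a chaotic map series (validation fixture)
#'
#' Iterates the logistic map `x -> r x (1 - x)` or the Henon map after a
#' 1000-step burn-in. Deterministic.
#'
#' @param map `"logistic"` or `"henon"`.
#' @param params named list: `r` for logistic (default 4); `a`, `b` for
#'   Henon (defaults 1.4, 0.3).
#' @param n series length.
#' @param x0 initial condition (scalar for logistic; length-2 for Henon,
#'   second element defaulting to 0).
#' @return numeric series of length `n` (the x-coordinate for Henon).
#' @export
gen_chaotic_series <- function(map = c("logistic", "henon"), params = list(),
                               n, x0 = 0.2) {
  map <- match.arg(map)
  if (n < 100) stop("n must be at least 100", call. = FALSE)
  burn <- 1000L
  if (map == "logistic") {
    r <- params$r %||% 4
    x <- x0[1]
    out <- numeric(n)
    for (i in seq_len(burn + n)) {
      x <- r * x * (1 - x)
      if (!is.finite(x) || abs(x) > 1e6)
        stop("divergent orbit", call. = FALSE)
      if (i > burn) out[i - burn] <- x
    }
    out
  } else {
    a <- params$a %||% 1.4
    b <- params$b %||% 0.3
    x <- x0[1]; y <- if (length(x0) > 1) x0[2] else 0
    out <- numeric(n)
    for (i in seq_len(burn + n)) {
      xn <- 1 - a * x^2 + y
      y <- b * x
      x <- xn
      if (!is.finite(x) || abs(x) > 1e6)
        stop("divergent orbit", call. = FALSE)
      if (i > burn) out[i - burn] <- x
    }
    out
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters for the synthetic cohort generator
#'
#' @param n_subjects cohort size.
#' @param healthy_fraction fraction assigned heart-failure stage 0/A
#'   (reference-group candidates); the rest are stage B-D.
#' @param betas named numeric vector of log-hazards per marker z-score
#'   (names must be marker names).
#' @param weibull_shape,weibull_scale baseline Weibull survival parameters
#'   (shape 1.2, scale chosen so that roughly 12% of a null cohort dies
#'   within the 8-year administrative window).
#' @param admin_censor_years administrative censoring horizon (default 8).
#' @param age_mean,age_sd,female_fraction covariate model.
#' @param marker_names markers for which z-scores are drawn (standard
#'   normal, independent).
#' @param hf_marker_shift mean z-score shift applied to the heart-failure
#'   group (negative values emulate depressed HRV); named vector or a
#'   single number applied to all markers.
#' @param rr_healthy,rr_hf `rr_gen_params` templates per group for signal
#'   mode.
#' @param mode `"markers"` (draw marker z-scores directly; fast, exact
#'   ground truth) or `"signal"` (also generate RR recordings per subject).
#' @param seed RNG seed.
#' @return object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_subjects, healthy_fraction = 0.3,
                              betas = c(ac = log(1.53), dc = log(0.70)),
                              weibull_shape = 1.2, weibull_scale = 40,
                              admin_censor_years = 8, age_mean = 64.5,
                              age_sd = 10.5, female_fraction = 0.354,
                              marker_names = names(betas),
                              hf_marker_shift = 0,
                              rr_healthy = NULL, rr_hf = NULL,
                              mode = c("markers", "signal"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_subjects >= 2, healthy_fraction > 0, healthy_fraction < 1,
            all(is.finite(betas)), weibull_shape > 0, weibull_scale > 0)
  if (is.null(names(betas)) || any(!nzchar(names(betas))))
    stop("betas must be a named vector", call. = FALSE)
  marker_names <- unique(c(marker_names, names(betas)))
  structure(list(n_subjects = as.integer(n_subjects),
                 healthy_fraction = healthy_fraction, betas = betas,
                 weibull_shape = weibull_shape,
                 weibull_scale = weibull_scale,
                 admin_censor_years = admin_censor_years,
                 age_mean = age_mean, age_sd = age_sd,
                 female_fraction = female_fraction,
                 marker_names = marker_names,
                 hf_marker_shift = hf_marker_shift,
                 rr_healthy = rr_healthy, rr_hf = rr_hf, mode = mode,
                 seed = seed),
            class = "cohort_gen_params")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per subject: a group label (healthy/at-risk vs heart failure), covariates
#' (age normal, sex Bernoulli), marker z-scores (standard normal, shifted by
#' `hf_marker_shift` in the heart-failure group), and a survival time drawn
#' from a Weibull proportional-hazards model whose linear predictor is
#' `sum(betas * z)`; events are censored administratively at
#' `admin_censor_years`. In `"signal"` mode each subject additionally
#' receives an RR recording from the group-specific generator template, with
#' the subject's LF/HF amplitudes scaled by their z-scores so the recordings
#' carry the configured between-subject variability.
#'
#' @param p a [cohort_gen_params].
#' @return list of class `synthetic_cohort`: `covariates` (data.frame with
#'   id, group, hf_stage, diabetes_10y_no_diet, neuro_disorder, age, sex,
#'   time_years, event), `markers` (data.frame of z-scores), `truth` (the
#'   generator parameters and per-subject linear predictors), and in signal
#'   mode `recordings` (list of [rr_series]) and `meta` (list of
#'   [record_meta]).
#' @export
gen_cohort <- function(p) {
  stopifnot(inherits(p, "cohort_gen_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  n <- p$n_subjects
  healthy <- stats::runif(n) < p$healthy_fraction
  group <- ifelse(healthy, "healthy", "heart_failure")
  hf_stage <- ifelse(healthy, sample(c("0", "A"), n, replace = TRUE),
                     sample(c("B", "C", "D"), n, replace = TRUE))
  age <- stats::rnorm(n, p$age_mean, p$age_sd)
  sex <- as.integer(stats::runif(n) < p$female_fraction)  # 1 = female
  m <- length(p$marker_names)
  Z <- matrix(stats::rnorm(n * m), n, m,
              dimnames = list(NULL, p$marker_names))
  shift <- p$hf_marker_shift
  if (length(shift) == 1L && is.null(names(shift)))
    shift <- stats::setNames(rep(shift, m), p$marker_names)
  for (mk in names(shift))
    if (mk %in% colnames(Z)) Z[!healthy, mk] <- Z[!healthy, mk] + shift[[mk]]
  lp <- drop(Z[, names(p$betas), drop = FALSE] %*% p$betas)
  u <- stats::runif(n)
  t_event <- p$weibull_scale * (-log(u) / exp(lp))^(1 / p$weibull_shape)
  time_years <- pmin(t_event, p$admin_censor_years)
  event <- as.integer(t_event <= p$admin_censor_years)
  covariates <- data.frame(
    id = sprintf("S%04d", seq_len(n)), group = group, hf_stage = hf_stage,
    diabetes_10y_no_diet = FALSE, neuro_disorder = FALSE, age = age,
    sex = sex, time_years = time_years, event = event,
    stringsAsFactors = FALSE)
  out <- list(covariates = covariates,
              markers = as.data.frame(Z),
              truth = list(params = unclass(p), linear_predictor = lp,
                           group = group))
  if (p$mode == "signal") {
    tpl_h <- p$rr_healthy %||% rr_gen_params(duration_h = 0.5)
    tpl_f <- p$rr_hf %||% rr_gen_params(duration_h = 0.5, a_lf = 12,
                                        a_hf = 7)
    recs <- vector("list", n)
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      tpl <- if (healthy[i]) tpl_h else tpl_f
      tpl$seed <- NULL
      # subject-level amplitude variability tied to the drawn z-scores
      sc <- exp(0.15 * Z[i, 1])
      tpl$a_lf <- tpl$a_lf * sc
      tpl$a_hf <- tpl$a_hf * sc
      recs[[i]] <- gen_rr_record(tpl, record_id = covariates$id[i])
      meta[[i]] <- record_meta(covariates$id[i],
                               wearing_time_h = tpl$duration_h)
    }
    out$recordings <- recs
    out$meta <- meta
  }
  if (sum(event) == 0L)
    warning("generated cohort has zero events; consider another seed or a ",
            "larger baseline hazard")
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d subjects (%d healthy), %d events, %d markers%s>\n",
    nrow(x$covariates), sum(x$covariates$group == "healthy"),
    sum(x$covariates$event), ncol(x$markers),
    if (!is.null(x$recordings)) ", with recordings" else ""))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits RR text files (signal mode), a metadata CSV, the covariate table,
#' the marker z-score table, and a ground-truth JSON with the generator
#' parameters, so downstream checks never re-derive the truth from the
#' pipeline under test.
#'
#' @param cohort a [gen_cohort] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(id = cohort$covariates$id, cohort$markers),
                   file.path(dir, "markers_true.csv"), row.names = FALSE)
  if (!is.null(cohort$recordings)) {
    rr_dir <- file.path(dir, "rr")
    dir.create(rr_dir, showWarnings = FALSE)
    for (r in cohort$recordings)
      write_rr_text(r, file.path(rr_dir, paste0(r$record_id, ".txt")))
    meta <- do.call(rbind, lapply(cohort$meta, function(m)
      data.frame(record_id = m$record_id, has_pacemaker = m$has_pacemaker,
                 af_fraction = m$af_fraction,
                 heart_transplant = m$heart_transplant,
                 wearing_time_h = m$wearing_time_h)))
    utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  }
  truth <- cohort$truth
  truth$params$rr_healthy <- unclass(truth$params$rr_healthy)
  truth$params$rr_hf <- unclass(truth$params$rr_hf)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
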
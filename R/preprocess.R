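#' Recording metadata for eligibility screening
#'
#' @param record_id recording identifier.
#' @param has_pacemaker logical; pacemaker stimulation present.
#' @param af_fraction fraction of the recording time spent in atrial
#'   fibrillation, in `[0, 1]`.
#' @param heart_transplant logical; heart transplant recipient.
#' @param wearing_time_h device wearing time in hours (>= 0).
#' @return an object of class `record_meta`.
#' @export
record_meta <- function(record_id, has_pacemaker = FALSE, af_fraction = 0,
                        heart_transplant = FALSE, wearing_time_h = 24) {
  af_fraction <- as.numeric(af_fraction)
  if (is.na(af_fraction) || af_fraction < 0 || af_fraction > 1)
    stop("af_fraction must lie in [0, 1]", call. = FALSE)
  wearing_time_h <- as.numeric(wearing_time_h)
  if (is.na(wearing_time_h) || wearing_time_h < 0)
    stop("wearing_time_h must be non-negative", call. = FALSE)
  structure(
    list(record_id = as.character(record_id),
         has_pacemaker = isTRUE(has_pacemaker),
         af_fraction = af_fraction,
         heart_transplant = isTRUE(heart_transplant),
         wearing_time_h = wearing_time_h),
    class = "record_meta"
  )
}

#' Eligibility decision for one recording
#'
#' A recording is excluded when the participant has pacemaker stimulation,
#' was in atrial fibrillation for at least half of the recording time, or
#' underwent heart transplantation. The decision is a pure function of the
#' metadata.
#'
#' @param meta a [record_meta].
#' @return a list with `included` (logical) and `reason` (`"included"`, or
#'   the first triggered rule among `"pacemaker"`, `"af"`, `"transplant"`).
#' @export
check_eligibility <- function(meta) {
  stopifnot(inherits(meta, "record_meta"))
  reason <-
    if (meta$has_pacemaker) "pacemaker"
    else if (meta$af_fraction >= 0.5) "af"
    else if (meta$heart_transplant) "transplant"
    else "included"
  list(record_id = meta$record_id, included = reason == "included",
       reason = reason)
}

#' Artifact-filter parameters
#'
#' Controls the running-median relative-deviation filter used by
#' [filter_to_nn]. A beat is rejected when its interval falls outside
#' `abs_bounds`, when it carries a non-normal annotation, or when it deviates
#' from the running median of the `window_beats` surrounding accepted beats
#' by more than `rel_threshold`.
#'
#' @param rel_threshold maximum relative deviation from the running reference
#'   (fraction in (0,1); default 0.2).
#' @param window_beats running-median window length in beats (odd, >= 3).
#' @param abs_bounds admissible interval range in ms, `c(lo, hi)`.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(rel_threshold = 0.2, window_beats = 11L,
                          abs_bounds = c(300, 2000)) {
  if (!(rel_threshold > 0 && rel_threshold < 1))
    stop("rel_threshold must lie in (0, 1)", call. = FALSE)
  window_beats <- as.integer(window_beats)
  if (window_beats < 3L || window_beats %% 2L == 0L)
    stop("window_beats must be odd and >= 3", call. = FALSE)
  abs_bounds <- as.numeric(abs_bounds)
  if (length(abs_bounds) != 2L || abs_bounds[1L] >= abs_bounds[2L])
    stop("abs_bounds must be an increasing pair", call. = FALSE)
  structure(list(rel_threshold = rel_threshold, window_beats = window_beats,
                 abs_bounds = abs_bounds),
            class = "filter_params")
}

#' Filter an RR series to normal-to-normal intervals
#'
#' Sequential artifact filter: each beat is compared against the running
#' median of the last `window_beats` accepted intervals (or all accepted
#' intervals so far, while fewer are available). Rejection rules, in order:
#' interval outside `abs_bounds`; beat annotated non-normal; relative
#' deviation from the running median exceeding `rel_threshold`. Accepted
#' beats keep their original timestamps, so rejected beats leave gaps in
#' elapsed time rather than shifting later beats. The filter is idempotent:
#' its output passes unchanged through a second application.
#'
#' @param rr an [rr_series].
#' @param params a [filter_params].
#' @return an [nn_series] with `rejected_count` set.
#' @export
filter_to_nn <- function(rr, params = filter_params()) {
  stopifnot(inherits(rr, "rr_series"), inherits(params, "filter_params"))
  x <- rr$intervals
  n <- length(x)
  non_normal <- if (is.null(rr$labels)) rep(FALSE, n) else rr$labels != "normal"
  keep <- cpp_median_filter(x, non_normal, params$abs_bounds[1L],
                            params$abs_bounds[2L], params$rel_threshold,
                            params$window_beats)
  if (!any(keep))
    stop("all beats rejected by the artifact filter for record ",
         rr$record_id, call. = FALSE)
  nn_series(x[keep], rr$beat_times[keep], record_id = rr$record_id,
            rejected_count = sum(!keep))
}

#' Uniformly resampled tachogram
#'
#' Interpolates the NN interval value as a function of beat time onto a
#' uniform grid spanning the recording, the standard prerequisite for
#' spectral analysis of heart rate variability. Cubic-spline interpolation
#' is the default: linear interpolation acts as a low-pass filter that
#' measurably attenuates spectral components approaching the beat rate
#' (e.g. the respiratory HF band at typical heart rates), biasing LF/HF
#' upward.
#'
#' @param nn an [nn_series] with at least 2 beats.
#' @param rate sampling rate in Hz (default 4, the HRV convention).
#' @param method interpolation method, `"cubic"` (natural spline, default)
#'   or `"linear"`.
#' @return an object of class `tachogram`: list with `values` (ms), `rate`
#'   (Hz) and `start_time` (s).
#' @export
resample_tachogram <- function(nn, rate = 4, method = c("cubic", "linear")) {
  stopifnot(inherits(nn, "nn_series"))
  method <- match.arg(method)
  if (length(nn$intervals) < 2L)
    stop("at least 2 beats are required to resample", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  t0 <- nn$beat_times[1L]
  t1 <- nn$beat_times[length(nn$beat_times)]
  grid <- seq(t0, t1, by = 1 / rate)
  vals <- if (method == "linear") {
    stats::approx(nn$beat_times, nn$intervals, xout = grid, rule = 2)$y
  } else {
    stats::spline(nn$beat_times, nn$intervals, xout = grid,
                  method = "natural")$y
  }
  structure(list(values = vals, rate = rate, start_time = t0),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram: %d samples @ %g Hz (%.2f h)>\n", length(x$values),
              x$rate, length(x$values) / x$rate / 3600))
  invisible(x)
}
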
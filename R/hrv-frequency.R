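#' Frequency band scheme
#'
#' Band edges for spectral HRV analysis. Defaults follow the long-standing
#' Task Force conventions, with the ULF upper edge at 1/300 Hz so that ULF
#' captures oscillations with periods of 5 minutes or longer: ULF (0, 1/300],
#' VLF (1/300, 0.04], LF (0.04, 0.15], HF (0.15, 0.40] Hz. Bands must be
#' contiguous, non-overlapping and increasing; membership of a frequency bin
#' is lower-exclusive / upper-inclusive, so the four bands partition
#' (0, hf upper].
#'
#' @param ulf,vlf,lf,hf numeric length-2 intervals `(lo, hi]` in Hz.
#' @return object of class `band_scheme`.
#' @export
band_scheme <- function(ulf = c(0, 1 / 300), vlf = c(1 / 300, 0.04),
                        lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  b <- list(ulf = as.numeric(ulf), vlf = as.numeric(vlf),
            lf = as.numeric(lf), hf = as.numeric(hf))
  edges <- unlist(b)
  if (any(vapply(b, length, 1L) != 2L) || any(diff(edges) < 0))
    stop("bands must be increasing length-2 intervals", call. = FALSE)
  if (!isTRUE(all.equal(b$ulf[2], b$vlf[1])) ||
      !isTRUE(all.equal(b$vlf[2], b$lf[1])) ||
      !isTRUE(all.equal(b$lf[2], b$hf[1])))
    stop("bands must be contiguous", call. = FALSE)
  structure(b, class = "band_scheme")
}

#' Spectral band powers of a tachogram
#'
#' Estimates the power spectral density of the (linearly detrended) tachogram
#' by Welch's method (default 5-minute Hann segments with 50% overlap) and
#' integrates it over the ULF, VLF, LF and HF bands. Total power is the
#' integral over (0, hf upper]; with the default contiguous bands the four
#' band powers sum exactly to the total. A band whose interval contains no
#' positive Fourier bin, or whose lower edge cannot be resolved by the
#' recording duration, is reported missing (`NA`). `lf_hf` is `NA` when HF
#' power is zero or missing.
#'
#' Note that with 5-minute segments the spectral resolution is 1/300 Hz, the
#' ULF upper edge: ULF power from this estimator rests on a single Fourier
#' bin. The time-resolved ULF summaries ([stft_band_series],
#' [wavelet_band_series]) use longer windows for that reason.
#'
#' @param tg a `tachogram` (see [resample_tachogram]).
#' @param bands a [band_scheme].
#' @param window_s Welch segment length in seconds (default 300).
#' @param overlap segment overlap fraction (default 0.5).
#' @return named list `ulf`, `vlf`, `lf`, `hf`, `total_power` (ms^2) and
#'   `lf_hf` (dimensionless).
#' @export
band_powers <- function(tg, bands = band_scheme(), window_s = 300,
                        overlap = 0.5) {
  stopifnot(inherits(tg, "tachogram"), inherits(bands, "band_scheme"))
  x <- detrend_linear(tg$values)
  dur <- length(x) / tg$rate
  spec <- welch_psd(x, tg$rate, nperseg = round(window_s * tg$rate),
                    overlap = overlap)
  one_band <- function(b) {
    need <- if (b[1] > 0) 2 / b[1] else 2 / b[2]
    if (dur < need) return(NA_real_)
    psd_band_power(spec, b[1], b[2])
  }
  out <- list(ulf = one_band(bands$ulf), vlf = one_band(bands$vlf),
              lf = one_band(bands$lf), hf = one_band(bands$hf))
  out$total_power <- psd_band_power(spec, 0, bands$hf[2])
  out$lf_hf <- if (is.na(out$lf) || is.na(out$hf) || out$hf == 0) NA_real_
               else out$lf / out$hf
  out
}

#' Short-time Fourier band-power track
#'
#' Slides a window of `window` seconds in steps of `shift` seconds across the
#' tachogram; each window is linearly detrended and its Hann periodogram
#' integrated over `band`. The ULF-Fourier marker of the study design is the
#' interquartile range (Q3 - Q1) of this track, see [ulf_fourier_marker].
#' Long windows (default 1800 s) are needed because a band of period >= 5 min
#' cannot be resolved by a 5-minute window.
#'
#' @param tg a `tachogram`.
#' @param band length-2 Hz interval `(lo, hi]`.
#' @param window window length in seconds (default 1800).
#' @param shift window step in seconds (default 300).
#' @return object of class `power_track`: list with `times` (window centres,
#'   s) and `power` (ms^2).
#' @export
stft_band_series <- function(tg, band = c(0, 1 / 300), window = 1800,
                             shift = 300) {
  stopifnot(inherits(tg, "tachogram"))
  if (band[1] > 0 && window < 2 / band[1])
    stop("window too short to resolve the band lower edge", call. = FALSE)
  n <- length(tg$values)
  wlen <- round(window * tg$rate)
  if (n < wlen)
    stop("tachogram shorter than one STFT window", call. = FALSE)
  step <- max(1L, round(shift * tg$rate))
  starts <- seq(1L, n - wlen + 1L, by = step)
  power <- vapply(starts, function(s) {
    spec <- periodogram_psd(tg$values[s:(s + wlen - 1L)], tg$rate)
    p <- psd_band_power(spec, band[1], band[2])
    if (is.na(p)) 0 else p
  }, numeric(1))
  structure(list(times = tg$start_time + (starts - 1L + wlen / 2) / tg$rate,
                 power = power),
            class = "power_track")
}

#' Wavelet band-power track
#'
#' Maximal-overlap discrete wavelet transform (LA8) of the linearly detrended
#' tachogram; the track is the per-time-point sum of squared detail
#' coefficients over the levels whose nominal dyadic frequency bands
#' intersect `band`. The ULF-wavelet marker of the study design is the median
#' of this track, see [ulf_wavelet_marker]. Frequencies below the deepest
#' resolvable level (limited by the recording length) fall into the smooth
#' and are not included.
#'
#' @param tg a `tachogram`.
#' @param band length-2 Hz interval.
#' @param wavelet filter family, `"la8"`.
#' @return a `power_track` (times in s, power in ms^2 per sample).
#' @export
wavelet_band_series <- function(tg, band = c(0, 1 / 300), wavelet = "la8") {
  stopifnot(inherits(tg, "tachogram"))
  x <- detrend_linear(tg$values)
  levels <- modwt_levels_for_band(band[1], band[2], tg$rate, length(x))
  w <- modwt(x, n_levels = max(levels), wavelet = wavelet)
  power <- rowSums(w$W[, levels, drop = FALSE]^2)
  structure(list(times = tg$start_time + (seq_along(x) - 1L) / tg$rate,
                 power = power),
            class = "power_track")
}

#' @export
print.power_track <- function(x, ...) {
  cat(sprintf("<power_track: %d points, median %.3g>\n", length(x$power),
              stats::median(x$power)))
  invisible(x)
}

#' ULF short-time-Fourier marker: IQR of the ULF STFT power track
#' @param track a `power_track` from [stft_band_series].
#' @return Q3 - Q1 of the track power.
#' @export
ulf_fourier_marker <- function(track) {
  q <- stats::quantile(track$power, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' ULF wavelet marker: median of the ULF wavelet power track
#' @param track a `power_track` from [wavelet_band_series].
#' @return median track power.
#' @export
ulf_wavelet_marker <- function(track) stats::median(track$power)
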
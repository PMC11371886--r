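#' The twenty HRV marker names, by domain
#'
#' Time domain: mean_hr, sdnn, sdann, rmssd, pnn50. Frequency domain: ulf,
#' vlf, lf, hf, lf_hf, total_power, ulf_fourier, ulf_wavelet. Non-linear:
#' ac, dc, time_lag, embedding_dim, fractal_dim, sample_entropy,
#' max_lyapunov.
#'
#' @return named character vector (names = domain).
#' @export
marker_names <- function() {
  c(time = "mean_hr", time = "sdnn", time = "sdann", time = "rmssd",
    time = "pnn50",
    frequency = "ulf", frequency = "vlf", frequency = "lf",
    frequency = "hf", frequency = "lf_hf", frequency = "total_power",
    frequency = "ulf_fourier", frequency = "ulf_wavelet",
    nonlinear = "ac", nonlinear = "dc", nonlinear = "time_lag",
    nonlinear = "embedding_dim", nonlinear = "fractal_dim",
    nonlinear = "sample_entropy", nonlinear = "max_lyapunov")
}

#' Compute all twenty HRV markers for one NN series
#'
#' Time- and frequency-domain markers are computed from the series and its
#' 4 Hz tachogram; non-linear markers are computed on the beat-domain NN
#' sequence to preserve beat-to-beat dynamics. Markers that cannot be
#' computed (recording too short for a band or window, no PRSA anchors,
#' no entropy template matches, ...) are reported as `NA` with the reason
#' collected in the `reasons` attribute — never as 0.
#'
#' @param nn an [nn_series].
#' @param bands a [band_scheme].
#' @param nl a [nonlinear_params].
#' @param rate tachogram sampling rate (Hz).
#' @param freq_window_s Welch segment length (s).
#' @param stft_window,stft_shift ULF short-time-Fourier window and step (s).
#' @return one-row data.frame with the 20 marker columns (see
#'   [marker_names]); attribute `reasons` is a named character vector for
#'   the missing ones.
#' @export
compute_markers <- function(nn, bands = band_scheme(),
                            nl = nonlinear_params(), rate = 4,
                            freq_window_s = 300, stft_window = 1800,
                            stft_shift = 300) {
  stopifnot(inherits(nn, "nn_series"))
  reasons <- character()
  note <- function(marker, reason) reasons[marker] <<- reason
  grab <- function(marker, expr) {
    v <- tryCatch(expr, error = function(e) {
      note(marker, conditionMessage(e))
      NA_real_
    })
    if (is.na(v) && !is.null(attr(v, "reason"))) note(marker, attr(v, "reason"))
    as.numeric(v)
  }
  td <- tryCatch(time_domain_markers(nn), error = function(e) {
    note("time_domain", conditionMessage(e))
    list(mean_hr = NA_real_, sdnn = NA_real_, sdann = NA_real_,
         rmssd = NA_real_, pnn50 = NA_real_)
  })
  if (is.na(td$sdann)) note("sdann", "fewer than 2 valid SDANN segments")

  tg <- tryCatch(resample_tachogram(nn, rate = rate),
                 error = function(e) NULL)
  if (is.null(tg)) {
    fm <- list(ulf = NA_real_, vlf = NA_real_, lf = NA_real_, hf = NA_real_,
               total_power = NA_real_, lf_hf = NA_real_)
    ulf_f <- NA_real_
    ulf_w <- NA_real_
    note("frequency_domain", "tachogram not computable")
  } else {
    fm <- band_powers(tg, bands, window_s = freq_window_s)
    for (b in c("ulf", "vlf", "lf", "hf"))
      if (is.na(fm[[b]])) note(b, "recording too short to resolve band")
    ulf_f <- grab("ulf_fourier",
                  ulf_fourier_marker(stft_band_series(
                    tg, bands$ulf, window = stft_window,
                    shift = stft_shift)))
    ulf_w <- grab("ulf_wavelet",
                  ulf_wavelet_marker(wavelet_band_series(tg, bands$ulf)))
  }

  ac <- grab("ac", prsa_capacity(nn, "acceleration", nl)$capacity)
  dc <- grab("dc", prsa_capacity(nn, "deceleration", nl)$capacity)
  lag <- tryCatch(time_lag(nn, nl), error = function(e) {
    note("time_lag", conditionMessage(e))
    NA_integer_
  })
  if (is.na(lag)) {
    emb <- NA_integer_; fd <- NA_real_; lyap <- NA_real_
    note("embedding_dim", "time lag unavailable")
    note("fractal_dim", "time lag unavailable")
    note("max_lyapunov", "time lag unavailable")
  } else {
    emb <- tryCatch(as.integer(embedding_dimension(nn, lag, nl)),
                    error = function(e) {
                      note("embedding_dim", conditionMessage(e))
                      NA_integer_
                    })
    m_use <- if (is.na(emb)) 2L else max(2L, emb)
    fd <- grab("fractal_dim", correlation_dimension(nn, m_use, lag, p = nl))
    lyap <- grab("max_lyapunov", max_lyapunov(nn, m_use, lag, p = nl))
  }
  sampen <- grab("sample_entropy", sample_entropy(nn, nl))

  out <- data.frame(
    mean_hr = td$mean_hr, sdnn = td$sdnn, sdann = td$sdann,
    rmssd = td$rmssd, pnn50 = td$pnn50,
    ulf = fm$ulf, vlf = fm$vlf, lf = fm$lf, hf = fm$hf, lf_hf = fm$lf_hf,
    total_power = fm$total_power, ulf_fourier = ulf_f, ulf_wavelet = ulf_w,
    ac = ac, dc = dc, time_lag = as.numeric(lag),
    embedding_dim = as.numeric(emb), fractal_dim = fd,
    sample_entropy = sampen, max_lyapunov = lyap)
  attr(out, "reasons") <- reasons
  out
}

#' Marker table for a list of NN series
#'
#' @param nn_list list of [nn_series].
#' @param ... passed to [compute_markers].
#' @return data.frame with an `id` column followed by the 20 marker
#'   columns; attribute `reasons` is a named list per record.
#' @export
marker_table <- function(nn_list, ...) {
  rows <- lapply(nn_list, function(nn) compute_markers(nn, ...))
  out <- do.call(rbind, rows)
  out <- cbind(id = vapply(nn_list, function(nn) nn$record_id, ""), out)
  rownames(out) <- NULL
  attr(out, "reasons") <- lapply(rows, attr, "reasons")
  out
}
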
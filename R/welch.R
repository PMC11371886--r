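# Welch power spectral density on a uniformly sampled series.
# One-sided PSD in ms^2/Hz; integral over frequency recovers variance.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- fs * sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2 / scale
    # fold negative frequencies into the one-sided density
    dbl <- 2L:(nfreq - if (nperseg %% 2L == 0L) 1L else 0L)
    sp[dbl] <- 2 * sp[dbl]
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg,
       psd = acc / length(starts),
       df = fs / nperseg)
}

# Single detrended Hann periodogram (used per STFT window)
periodogram_psd <- function(x, fs) {
  welch_psd(detrend_linear(x), fs, nperseg = length(x), overlap = 0)
}

# integral of the PSD over (lo, hi]: rectangle rule over bin frequencies
psd_band_power <- function(spec, lo, hi) {
  sel <- spec$freq > lo & spec$freq <= hi
  if (!any(sel)) return(NA_real_)
  sum(spec$psd[sel]) * spec$df
}
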
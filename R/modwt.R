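# Maximal-overlap discrete wavelet transform (MODWT), pyramid algorithm with
# circular boundary handling. Only the LA8 (least-asymmetric, 8-tap) family is
# shipped; level-j detail coefficients have nominal frequency band
# (fs/2^(j+1), fs/2^j].

la8_scaling <- c(
  -0.0757657147892733, -0.0296355276459985, 0.4976186676320155,
   0.8037387518059161,  0.2978577956052774, -0.0992195435768472,
  -0.0126039672620378,  0.0322231006040427
)

modwt_filters <- function(wavelet = "la8") {
  if (!identical(wavelet, "la8"))
    stop("only the 'la8' wavelet is available", call. = FALSE)
  g <- la8_scaling
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1L) * rev(g)   # quadrature mirror filter
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# equivalent filter length at level j for an L-tap base filter
modwt_support <- function(j, L = 8L) (2^j - 1L) * (L - 1L) + 1L

modwt_max_level <- function(n, L = 8L) {
  j <- 0L
  while (modwt_support(j + 1L, L) <= n) j <- j + 1L
  j
}

#' Maximal-overlap discrete wavelet transform
#'
#' Pyramid-algorithm MODWT with circular boundary treatment. Returns the
#' detail (wavelet) coefficients for levels `1..n_levels` and the final
#' smooth, each time-aligned with the input series.
#'
#' @param x numeric series.
#' @param n_levels number of decomposition levels; the equivalent filter
#'   support at the deepest level must not exceed `length(x)`.
#' @param wavelet filter family; `"la8"` (least-asymmetric, 8 taps).
#' @return list with `W` (matrix `length(x)` x `n_levels` of detail
#'   coefficients), `V` (final smooth), `wavelet`, `n_levels`.
#' @export
modwt <- function(x, n_levels, wavelet = "la8") {
  f <- modwt_filters(wavelet)
  n <- length(x)
  if (modwt_support(n_levels, f$L) > n)
    stop(sprintf(
      "series too short for MODWT level %d (filter support %d > %d samples)",
      n_levels, modwt_support(n_levels, f$L), n), call. = FALSE)
  W <- matrix(0, n, n_levels)
  V <- x
  idx0 <- seq_len(n)
  for (j in seq_len(n_levels)) {
    stride <- 2^(j - 1L)
    Wj <- numeric(n)
    Vj <- numeric(n)
    for (l in seq_len(f$L) - 1L) {
      src <- ((idx0 - 1L - l * stride) %% n) + 1L
      Wj <- Wj + f$h[l + 1L] * V[src]
      Vj <- Vj + f$g[l + 1L] * V[src]
    }
    W[, j] <- Wj
    V <- Vj
  }
  list(W = W, V = V, wavelet = wavelet, n_levels = n_levels)
}

# wavelet levels whose nominal band (fs/2^(j+1), fs/2^j] intersects (lo, hi]
modwt_levels_for_band <- function(lo, hi, fs, n, L = 8L) {
  jmax <- modwt_max_level(n, L)
  if (jmax < 1L)
    stop("series too short for any MODWT level", call. = FALSE)
  js <- seq_len(jmax)
  f_lo <- fs / 2^(js + 1)
  f_hi <- fs / 2^js
  sel <- js[f_lo < hi & f_hi > lo]
  if (length(sel) == 0L)
    stop(sprintf(
      paste0("band (%g, %g] Hz not resolvable at %g Hz sampling: available ",
             "levels span finest %d (%.4g-%.4g Hz) to coarsest %d ",
             "(%.4g-%.4g Hz)"),
      lo, hi, fs, 1L, fs / 4, fs / 2, jmax, fs / 2^(jmax + 1), fs / 2^jmax),
      call. = FALSE)
  sel
}
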
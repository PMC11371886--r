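#' Parameters for the non-linear HRV markers
#'
#' Bundles the tuning constants of the seven non-linear estimators. Units are
#' milliseconds for amplitude-like quantities and beats for index-like ones.
#'
#' @param prsa_L phase-rectified signal averaging half-window in beats; the
#'   capacity uses offsets `-2..1` so `L = 2` suffices.
#' @param prsa_max_rel_change anchor filter: beats whose interval changes by
#'   more than this fraction of the preceding interval are not anchors.
#' @param acf_threshold autocorrelation threshold for the time lag
#'   (default `1/e`).
#' @param max_lag largest lag searched for the time lag (beats).
#' @param cao_threshold saturation level for Cao's E1 statistic.
#' @param max_dim largest embedding dimension tried.
#' @param sampen_m sample-entropy template length.
#' @param sampen_r_frac sample-entropy tolerance as a fraction of the series
#'   SD.
#' @param lyap_radius neighbourhood radius for the Rosenstein Lyapunov
#'   estimator, in series units (ms for NN series).
#' @param theiler_window temporal exclusion window in beats for neighbour
#'   searches; `NULL` means use the time lag.
#' @param lyap_fit_range iterations (beats) over which the divergence slope
#'   is fitted.
#' @param max_points cap on the number of points entering the O(n^2)
#'   estimators (correlation dimension, sample entropy, Cao, Rosenstein);
#'   longer series are truncated to their first `max_points` beats.
#' @param cao_n_ref number of reference points for Cao's E statistic.
#' @return object of class `nonlinear_params`.
#' @export
nonlinear_params <- function(prsa_L = 2L, prsa_max_rel_change = 0.05,
                             acf_threshold = exp(-1), max_lag = 50L,
                             cao_threshold = 0.95, max_dim = 15L,
                             sampen_m = 2L, sampen_r_frac = 0.2,
                             lyap_radius = 100, theiler_window = NULL,
                             lyap_fit_range = 1:10, max_points = 10000L,
                             cao_n_ref = 1000L) {
  stopifnot(prsa_L >= 1, prsa_max_rel_change > 0, acf_threshold > 0,
            max_lag >= 1, cao_threshold > 0, cao_threshold < 1, max_dim >= 2,
            sampen_m >= 1, sampen_r_frac > 0, sampen_r_frac < 1,
            lyap_radius > 0, max_points >= 100, cao_n_ref >= 10)
  structure(list(prsa_L = as.integer(prsa_L),
                 prsa_max_rel_change = prsa_max_rel_change,
                 acf_threshold = acf_threshold, max_lag = as.integer(max_lag),
                 cao_threshold = cao_threshold, max_dim = as.integer(max_dim),
                 sampen_m = as.integer(sampen_m),
                 sampen_r_frac = sampen_r_frac, lyap_radius = lyap_radius,
                 theiler_window = theiler_window,
                 lyap_fit_range = as.integer(lyap_fit_range),
                 max_points = as.integer(max_points),
                 cao_n_ref = as.integer(cao_n_ref)),
            class = "nonlinear_params")
}

missing_marker <- function(reason) {
  structure(NA_real_, reason = reason)
}

as_series <- function(x) {
  if (inherits(x, "nn_series")) x$intervals else as.numeric(x)
}

cap_series <- function(x, p) {
  if (length(x) > p$max_points) x[seq_len(p$max_points)] else x
}

#' Phase-rectified signal averaging: acceleration / deceleration capacity
#'
#' Anchors are beats whose NN interval lengthens (deceleration) or shortens
#' (acceleration) relative to the previous beat, excluding changes larger
#' than `prsa_max_rel_change` of the preceding interval and anchors whose
#' `-L..L-1` window leaves the series. The profile is the anchor-wise mean of
#' the NN interval at each offset, and the capacity is the Haar-like contrast
#' `(X(0) + X(1) - X(-1) - X(-2)) / 4`, positive for deceleration capacity
#' and typically negative for acceleration capacity.
#'
#' @param nn an [nn_series] (or numeric NN vector).
#' @param direction `"deceleration"` or `"acceleration"`.
#' @param p a [nonlinear_params].
#' @return list with `capacity` (ms; `NA` with a `reason` attribute when no
#'   valid anchors exist) and `profile` (list with `window_offsets`,
#'   `profile`, `anchor_count`, `direction`).
#' @export
prsa_capacity <- function(nn, direction = c("deceleration", "acceleration"),
                          p = nonlinear_params()) {
  direction <- match.arg(direction)
  x <- as_series(nn)
  L <- p$prsa_L
  if (length(x) < 2 * L + 2)
    stop("series too short for PRSA (need >= 2L + 2 beats)", call. = FALSE)
  i <- 2:length(x)
  dx <- x[i] - x[i - 1]
  is_anchor <- if (direction == "deceleration") dx > 0 else dx < 0
  is_anchor <- is_anchor & abs(dx) <= p$prsa_max_rel_change * x[i - 1]
  anchors <- i[is_anchor]
  anchors <- anchors[anchors - L >= 1 & anchors + L - 1 <= length(x)]
  if (length(anchors) == 0L) {
    return(list(capacity = missing_marker("no valid PRSA anchors"),
                profile = NULL))
  }
  offsets <- (-L):(L - 1)
  prof <- vapply(offsets, function(k) mean(x[anchors + k]), numeric(1))
  names(prof) <- offsets
  capacity <- (prof["0"] + prof["1"] - prof["-1"] - prof["-2"]) / 4
  list(capacity = unname(capacity),
       profile = list(window_offsets = offsets, profile = unname(prof),
                      anchor_count = length(anchors), direction = direction))
}

#' Time lag: first autocorrelation decay
#'
#' The smallest lag at which the series' sample autocorrelation drops below
#' the threshold (default `1/e`): how far the series must be shifted against
#' itself before consecutive values are no longer strongly correlated.
#' Alternative criteria: first non-positive value (`"first_zero"`) or first
#' local minimum (`"first_minimum"`).
#'
#' @param nn an [nn_series] or numeric vector.
#' @param p a [nonlinear_params].
#' @param criterion decorrelation criterion.
#' @return integer lag in beats; when the criterion is never met, `max_lag`
#'   with attribute `saturated = TRUE`.
#' @export
time_lag <- function(nn, p = nonlinear_params(),
                     criterion = c("threshold", "first_zero",
                                   "first_minimum")) {
  criterion <- match.arg(criterion)
  x <- as_series(nn)
  if (length(x) < p$max_lag + 2)
    stop("series too short for the requested max_lag", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("time lag undefined for a zero-variance series", call. = FALSE)
  rho <- as.vector(stats::acf(x, lag.max = p$max_lag, plot = FALSE,
                              demean = TRUE)$acf)[-1]
  k <- switch(criterion,
    threshold = which(rho < p$acf_threshold),
    first_zero = which(rho <= 0),
    first_minimum = which(diff(rho) > 0)
  )
  if (length(k) == 0L)
    return(structure(p$max_lag, saturated = TRUE))
  as.integer(k[1L])
}

#' Embedding dimension by Cao's method
#'
#' Computes Cao's `E1(d) = E(d+1)/E(d)` for `d = 1..max_dim`, where `E(d)` is
#' the mean ratio of the (d+1)- to d-dimensional Chebyshev distance between
#' each point and its d-dimensional nearest neighbour. Returns the smallest
#' `d` with `E1(d) >= cao_threshold` and `|E1(d+1) - E1(d)| < 1 -
#' cao_threshold`; if E1 never saturates (as for stochastic series), returns
#' `max_dim` with attribute `saturated = TRUE`.
#'
#' @param series numeric series or [nn_series].
#' @param lag embedding delay in beats (e.g. from [time_lag]).
#' @param p a [nonlinear_params].
#' @return integer dimension, with attributes `E1` (the E1 curve) and, when
#'   saturation never occurs, `saturated = TRUE`.
#' @export
embedding_dimension <- function(series, lag, p = nonlinear_params()) {
  x <- cap_series(as_series(series), p)
  lag <- as.integer(lag)
  if (length(x) < (p$max_dim + 1L) * lag + 10L)
    stop("series too short for Cao's method at max_dim", call. = FALSE)
  E <- vapply(seq_len(p$max_dim + 2L), function(d)
    cpp_cao_E(x, lag, d, p$cao_n_ref), numeric(1))
  E1 <- E[-1] / E[-length(E)]           # E1(d) for d = 1..max_dim+1
  for (d in seq_len(p$max_dim)) {
    if (!is.na(E1[d]) && !is.na(E1[d + 1]) &&
        E1[d] >= p$cao_threshold &&
        abs(E1[d + 1] - E1[d]) < 1 - p$cao_threshold)
      return(structure(as.integer(d), E1 = E1[seq_len(p$max_dim)]))
  }
  structure(p$max_dim, saturated = TRUE, E1 = E1[seq_len(p$max_dim)])
}

#' Correlation (fractal) dimension, Grassberger-Procaccia
#'
#' Correlation sums `C(r)` over log-spaced radii with Theiler exclusion; the
#' dimension estimate is the least-squares slope of `log C(r)` versus
#' `log r` over the scaling region. By default the radii are log-spaced
#' between small and moderate quantiles of a subsample of pairwise distances,
#' and the fit uses radii with `C(r)` between `scaling_c[1]` and
#' `scaling_c[2]` (away from both the discreteness floor and saturation).
#'
#' @param series numeric series or [nn_series].
#' @param m embedding dimension.
#' @param lag embedding delay (beats).
#' @param radii optional radii (series units, increasing); derived from the
#'   data when `NULL`.
#' @param p a [nonlinear_params].
#' @param n_radii number of automatic radii.
#' @param scaling_c C(r) range defining the scaling region for the slope fit.
#' @return slope estimate (dimensionless), with attributes `radii` and
#'   `C`. `NA` with a reason when fewer than 3 radii have positive counts.
#' @export
correlation_dimension <- function(series, m, lag, radii = NULL,
                                  p = nonlinear_params(), n_radii = 24L,
                                  scaling_c = c(5e-4, 0.2)) {
  x <- cap_series(as_series(series), p)
  m <- as.integer(m); lag <- as.integer(lag)
  if (length(x) < (m - 1L) * lag + 2L)
    stop("series too short to embed", call. = FALSE)
  theiler <- theiler_of(p, lag)
  if (is.null(radii)) {
    np <- length(x) - (m - 1L) * lag
    ii <- floor(seq(1, np, length.out = min(200L, np)))
    emb <- vapply(seq_len(m) - 1L, function(k) x[ii + k * lag],
                  numeric(length(ii)))
    dd <- as.vector(stats::dist(emb, method = "maximum"))
    dd <- dd[dd > 0]
    if (length(dd) < 10L)
      return(missing_marker("degenerate series: no positive distances"))
    radii <- exp(seq(log(stats::quantile(dd, 0.001, names = FALSE)),
                     log(stats::quantile(dd, 0.75, names = FALSE)),
                     length.out = n_radii))
  }
  radii <- sort(as.numeric(radii))
  C <- cpp_corr_sums(x, m, lag, radii, theiler)
  pos <- which(C > 0)
  if (length(pos) < 3L)
    return(missing_marker("fewer than 3 radii with positive correlation sum"))
  sel <- pos[C[pos] >= scaling_c[1] & C[pos] <= scaling_c[2]]
  if (length(sel) < 3L) sel <- pos          # degenerate: fit over all positive
  if (stats::sd(log(C[sel])) == 0)
    return(structure(0, radii = radii, C = C))  # e.g. repeated single point
  fit <- stats::lm.fit(cbind(1, log(radii[sel])), log(C[sel]))
  structure(unname(fit$coefficients[2]), radii = radii, C = C)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A/B)` with `A` the number of template matches of
#' length `m + 1` and `B` of length `m`, Chebyshev distance, self-matches
#' excluded, tolerance `r = sampen_r_frac * SD(series)`.
#'
#' @param series numeric series or [nn_series].
#' @param p a [nonlinear_params].
#' @return entropy in nats; `NA` with a reason when no (m+1)-matches exist.
#' @export
sample_entropy <- function(series, p = nonlinear_params()) {
  x <- cap_series(as_series(series), p)
  m <- p$sampen_m
  if (length(x) <= m + 1L)
    stop("series too short for sample entropy", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0)
    stop("sample entropy undefined for a zero-variance series", call. = FALSE)
  cnt <- cpp_sampen_counts(x, m, p$sampen_r_frac * s)
  if (cnt[2] == 0)
    return(missing_marker("no template matches of length m"))
  if (cnt[1] == 0)
    return(missing_marker("no template matches of length m + 1"))
  -log(cnt[1] / cnt[2])
}

#' Maximal Lyapunov exponent, Rosenstein estimator
#'
#' For each embedded point the nearest neighbour (Euclidean) outside the
#' Theiler window and within `lyap_radius` is tracked forward; the exponent
#' is the least-squares slope of the mean log divergence over
#' `lyap_fit_range` iterations, in units of 1/beat.
#'
#' @param series numeric series or [nn_series].
#' @param m embedding dimension.
#' @param lag embedding delay (beats).
#' @param p a [nonlinear_params].
#' @return exponent per beat (may be negative), with attribute
#'   `mean_log_div`; `NA` with a reason when more than 90% of points have no
#'   neighbour within the radius.
#' @export
max_lyapunov <- function(series, m, lag, p = nonlinear_params()) {
  x <- cap_series(as_series(series), p)
  m <- as.integer(m); lag <- as.integer(lag)
  if (length(x) < (m - 1L) * lag + 2L)
    stop("series too short to embed", call. = FALSE)
  theiler <- theiler_of(p, lag)
  kmax <- max(p$lyap_fit_range)
  res <- cpp_rosenstein(x, m, lag, p$lyap_radius, theiler, kmax)
  if (res$frac_no_neighbor > 0.9)
    return(missing_marker(sprintf(
      "no neighbour within radius %g for %.0f%% of points", p$lyap_radius,
      100 * res$frac_no_neighbor)))
  k <- p$lyap_fit_range
  y <- res$mean_log_div[k + 1L]
  ok <- !is.na(y)
  if (sum(ok) < 2L)
    return(missing_marker("divergence curve too short to fit"))
  fit <- stats::lm.fit(cbind(1, k[ok]), y[ok])
  structure(unname(fit$coefficients[2]), mean_log_div = res$mean_log_div)
}

theiler_of <- function(p, lag) {
  if (is.null(p$theiler_window)) as.integer(lag) else
    as.integer(p$theiler_window)
}
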
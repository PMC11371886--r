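#' Time-domain HRV markers
#'
#' Computes the five time-domain markers from an NN series:
#' \describe{
#'   \item{mean_hr}{mean heart rate, `60000 / mean(NN)` in beats/min.}
#'   \item{sdnn}{sample standard deviation (n-1 denominator) of all NN (ms).}
#'   \item{sdann}{sample SD of per-segment mean NN over consecutive
#'     `segment_len`-second windows of elapsed time (ms). Segments whose
#'     summed interval time is below `min_segment_fill * segment_len`
#'     (e.g. from rejected-beat gaps) are discarded; with fewer than two
#'     valid segments SDANN is `NA`.}
#'   \item{rmssd}{root mean square of successive NN differences (ms).}
#'   \item{pnn50}{percentage of successive differences strictly exceeding
#'     50 ms.}
#' }
#' Segments are anchored at the first accepted beat; beat timestamps are
#' elapsed seconds, so the markers are invariant under time shift.
#'
#' @param nn an [nn_series] with at least 2 intervals.
#' @param segment_len SDANN segment length in seconds (default 300).
#' @param min_segment_fill minimum fraction of a segment covered by accepted
#'   intervals for it to count (default 0.5).
#' @return named list with `mean_hr`, `sdnn`, `sdann`, `rmssd`, `pnn50`.
#' @export
time_domain_markers <- function(nn, segment_len = 300, min_segment_fill = 0.5) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$intervals
  if (length(x) < 2L)
    stop("at least 2 NN intervals required", call. = FALSE)
  d <- diff(x)
  out <- list(
    mean_hr = 60000 / mean(x),
    sdnn = stats::sd(x),
    sdann = NA_real_,
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * mean(abs(d) > 50)
  )
  # SDANN over contiguous elapsed-time windows from the first beat
  elapsed <- nn$beat_times - nn$beat_times[1L]
  seg <- floor(elapsed / segment_len)
  seg_means <- tapply(x, seg, mean)
  seg_fill <- tapply(x, seg, sum) / 1000 / segment_len
  valid <- seg_fill >= min_segment_fill
  if (sum(valid) >= 2L)
    out$sdann <- stats::sd(seg_means[valid])
  out
}
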
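#' RR-interval series
#'
#' Container for a raw RR-interval recording: interbeat intervals in
#' milliseconds with (optionally) the cumulative beat times in seconds and a
#' per-beat annotation. When beat times are not supplied they are
#' reconstructed as the cumulative sum of the intervals.
#'
#' @param intervals numeric vector of RR intervals in ms (all > 0).
#' @param beat_times optional numeric vector of beat timestamps in seconds,
#'   strictly increasing, same length as `intervals`.
#' @param record_id character scalar identifying the recording.
#' @param labels optional character vector of per-beat annotations, one of
#'   `"normal"`, `"ectopic"`, `"artifact"`, `"af"`.
#' @return an object of class `rr_series`: a list with fields `record_id`,
#'   `intervals`, `beat_times`, `labels`.
#' @export
rr_series <- function(intervals, beat_times = NULL, record_id = "record",
                      labels = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("empty RR series", call. = FALSE)
  if (anyNA(intervals) || any(intervals <= 0))
    stop("all RR intervals must be positive and non-missing", call. = FALSE)
  if (is.null(beat_times)) {
    beat_times <- cumsum(intervals) / 1000
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(intervals))
      stop("beat_times and intervals must have equal length", call. = FALSE)
    if (any(diff(beat_times) <= 0))
      stop("beat_times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(intervals))
      stop("labels must match intervals in length", call. = FALSE)
    bad <- setdiff(unique(labels), c("normal", "ectopic", "artifact", "af"))
    if (length(bad))
      stop("unknown beat labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(record_id = as.character(record_id), intervals = intervals,
         beat_times = beat_times, labels = labels),
    class = "rr_series"
  )
}

#' Normal-to-normal interval series
#'
#' Result of artifact filtering an [rr_series]: the accepted (normal) beats
#' only, with the count of rejected beats retained for bookkeeping.
#'
#' @param intervals accepted NN intervals (ms).
#' @param beat_times timestamps of the accepted beats (s), strictly increasing.
#' @param record_id recording identifier.
#' @param rejected_count number of input beats that were rejected.
#' @return an object of class `nn_series`.
#' @export
nn_series <- function(intervals, beat_times, record_id = "record",
                      rejected_count = 0L) {
  intervals <- as.numeric(intervals)
  beat_times <- as.numeric(beat_times)
  if (length(intervals) == 0L) stop("empty NN series", call. = FALSE)
  if (any(intervals <= 0)) stop("NN intervals must be positive", call. = FALSE)
  if (length(beat_times) != length(intervals))
    stop("beat_times and intervals must have equal length", call. = FALSE)
  if (any(diff(beat_times) <= 0))
    stop("beat_times must be strictly increasing", call. = FALSE)
  structure(
    list(record_id = as.character(record_id), intervals = intervals,
         beat_times = beat_times, rejected_count = as.integer(rejected_count)),
    class = "nn_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series '%s': %d beats, %.2f h>\n", x$record_id,
              length(x$intervals), diff(range(x$beat_times)) / 3600))
  invisible(x)
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series '%s': %d NN beats (%d rejected), %.2f h>\n",
              x$record_id, length(x$intervals), x$rejected_count,
              diff(range(x$beat_times)) / 3600))
  invisible(x)
}

#' Read an RR recording from a plain-text file
#'
#' Two dialects are supported: `"intervals_ms"`, one interval in milliseconds
#' per line (Kubios / HRV-toolkit style), and `"time_interval_csv"`, a
#' two-column CSV with header columns `time_s` and `rr_ms` (or headerless
#' two-column numeric rows read as time, interval).
#'
#' @param path file path.
#' @param dialect `"intervals_ms"` (default) or `"time_interval_csv"`.
#' @param record_id identifier; defaults to the file name without extension.
#' @return an [rr_series].
#' @export
read_rr_text <- function(path, dialect = c("intervals_ms", "time_interval_csv"),
                         record_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty RR file: ", path, call. = FALSE)
  if (dialect == "intervals_ms") {
    vals <- suppressWarnings(as.numeric(trimws(lines)))
    if (anyNA(vals))
      stop(sprintf("non-numeric RR value at line %d of %s",
                   which(is.na(vals))[1L], path), call. = FALSE)
    rr_series(vals, record_id = record_id)
  } else {
    has_header <- grepl("[A-Za-z]", lines[1L])
    body <- if (has_header) lines[-1L] else lines
    if (length(body) == 0L) stop("empty RR file: ", path, call. = FALSE)
    parts <- strsplit(body, ",", fixed = TRUE)
    bad_shape <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad_shape))
      stop(sprintf("expected two comma-separated columns at line %d of %s",
                   bad_shape[1L] + has_header, path), call. = FALSE)
    tt <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 1L))))
    rr <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 2L))))
    bad <- which(is.na(tt) | is.na(rr))
    if (length(bad))
      stop(sprintf("non-numeric RR value at line %d of %s",
                   bad[1L] + has_header, path), call. = FALSE)
    rr_series(rr, beat_times = tt, record_id = record_id)
  }
}

#' Write an NN (or RR) series to plain text
#'
#' One interval in milliseconds per line, the same format [read_rr_text]
#' accepts with `dialect = "intervals_ms"`.
#'
#' @param x an [nn_series] or [rr_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rr_text <- function(x, path) {
  stopifnot(inherits(x, c("nn_series", "rr_series")))
  writeLines(format(x$intervals, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
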
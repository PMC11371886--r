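#' Percentile with linear interpolation between order statistics
#'
#' The quantile at probability `p` by linear interpolation at position
#' `p * (n - 1)` (0-based) between order statistics — the convention used
#' throughout the reference-range machinery (identical to R's default
#' `quantile` type 7).
#'
#' @param values numeric vector (missing values removed).
#' @param p probability in `[0, 1]` (vectorised).
#' @return quantile value(s).
#' @export
percentile <- function(values, p) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  stats::quantile(values, p, names = FALSE, type = 7)
}

#' Healthy / reference-group mask from a cohort covariate table
#'
#' The reference group is participants classified as healthy or at risk
#' (heart-failure stage 0 or A), excluding those with diabetes mellitus
#' diagnosed 10 or more years ago who are not receiving dietary treatment,
#' and those with degenerative or structural neurological disorders.
#'
#' @param covariates data.frame with columns `hf_stage` (one of
#'   `"0","A","B","C","D"`), `diabetes_10y_no_diet` (logical) and
#'   `neuro_disorder` (logical).
#' @return logical vector.
#' @export
healthy_mask <- function(covariates) {
  need <- c("hf_stage", "diabetes_10y_no_diet", "neuro_disorder")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("covariate table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  covariates$hf_stage %in% c("0", "A") &
    !isTRUE_vec(covariates$diabetes_10y_no_diet) &
    !isTRUE_vec(covariates$neuro_disorder)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Derive a reference range for one marker
#'
#' Bounds are the 5th and 95th percentiles (by default) of the marker among
#' reference-group subjects, missing values skipped.
#'
#' @param cohort_markers data.frame of marker values, one row per subject.
#' @param healthy_mask logical vector selecting the reference subjects.
#' @param marker marker column name.
#' @param lower_p,upper_p percentile bounds (defaults 0.05, 0.95).
#' @param min_n smallest acceptable number of non-missing reference values.
#' @return object of class `reference_range`: list with `marker`, `lower`,
#'   `upper`, `lower_p`, `upper_p`, `n_reference`, `convention`.
#' @export
derive_reference_range <- function(cohort_markers, healthy_mask, marker,
                                   lower_p = 0.05, upper_p = 0.95,
                                   min_n = 20L) {
  stopifnot(marker %in% names(cohort_markers),
            length(healthy_mask) == nrow(cohort_markers))
  v <- cohort_markers[[marker]][healthy_mask]
  v <- v[!is.na(v)]
  if (length(v) < min_n)
    stop(sprintf(
      "only %d non-missing reference values for '%s' (floor %d)",
      length(v), marker, min_n), call. = FALSE)
  b <- percentile(v, c(lower_p, upper_p))
  structure(list(marker = marker, lower = b[1], upper = b[2],
                 lower_p = lower_p, upper_p = upper_p,
                 n_reference = length(v),
                 convention = "linear interpolation at p(n-1)"),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("<reference_range %s: [%g, %g] (p %g/%g, n = %d)>\n",
              x$marker, x$lower, x$upper, x$lower_p, x$upper_p,
              x$n_reference))
  invisible(x)
}

#' Classify values against a reference range
#'
#' Bounds are inclusive: a value equal to a bound is `"inside"`; `"below"`
#' and `"above"` are strict. Missing values propagate as `NA`.
#'
#' @param value numeric vector.
#' @param range a [derive_reference_range] result.
#' @return factor with levels `below`, `inside`, `above`.
#' @export
classify_against_range <- function(value, range) {
  stopifnot(inherits(range, "reference_range"))
  out <- ifelse(is.na(value), NA_character_,
                ifelse(value < range$lower, "below",
                       ifelse(value > range$upper, "above", "inside")))
  factor(out, levels = c("below", "inside", "above"))
}

#' Tertile cut points and group assignment
#'
#' Cut points are the 1/3 and 2/3 quantiles (same convention as
#' [percentile]); groups are lowest (`<= t1`), middle (`> t1` and `<= t2`)
#' and highest (`> t2`).
#'
#' @param values numeric vector with at least 3 non-missing values.
#' @return list with `cutpoints` `c(t1, t2)` and `assignment`, a factor with
#'   levels `lowest`, `middle`, `highest` (NA for missing input).
#' @export
tertile_cutpoints <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) stop("need at least 3 non-missing values",
                           call. = FALSE)
  cp <- percentile(v, c(1 / 3, 2 / 3))
  g <- ifelse(is.na(values), NA_character_,
              ifelse(values <= cp[1], "lowest",
                     ifelse(values <= cp[2], "middle", "highest")))
  list(cutpoints = cp,
       assignment = factor(g, levels = c("lowest", "middle", "highest")))
}

#' Distribution summary of a marker, optionally against a reference range
#'
#' Quantile summary (median, quartiles, 5th/95th percentiles) plus, when a
#' reference range is supplied, the counts and percentages of values below,
#' above and outside the range — the layout of a cohort reference-value
#' table.
#'
#' @param values numeric vector.
#' @param range optional [derive_reference_range] result.
#' @return named list: `n`, `median`, `q1`, `q3`, `p5`, `p95`, and with a
#'   range also `n_below`, `n_above`, `n_outside`, `pct_below`, `pct_above`,
#'   `pct_outside`.
#' @export
distribution_summary <- function(values, range = NULL) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("no non-missing values", call. = FALSE)
  q <- percentile(v, c(0.5, 0.25, 0.75, 0.05, 0.95))
  out <- list(n = length(v), median = q[1], q1 = q[2], q3 = q[3],
              p5 = q[4], p95 = q[5])
  if (!is.null(range)) {
    fl <- classify_against_range(v, range)
    nb <- sum(fl == "below"); na_ <- sum(fl == "above")
    out$n_below <- nb
    out$n_above <- na_
    out$n_outside <- nb + na_
    out$pct_below <- 100 * nb / length(v)
    out$pct_above <- 100 * na_ / length(v)
    out$pct_outside <- 100 * (nb + na_) / length(v)
  }
  out
}
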
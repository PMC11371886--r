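#' Standardize columns by their sample standard deviation
#'
#' Divides each column by its sample SD without centering, so that model
#' coefficients are per-SD effects. (For Cox models and for slope terms in
#' linear models, centering is immaterial.)
#'
#' @param m numeric matrix or data.frame.
#' @return list with `z` (scaled matrix) and `sd` (named vector of the
#'   divisors, for back-transformation).
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  zero <- names(sds)[!is.na(sds) & sds == 0]
  if (length(zero))
    stop("zero-SD column(s): ", paste(zero, collapse = ", "), call. = FALSE)
  list(z = sweep(m, 2, sds, "/"), sd = sds)
}

#' Cox proportional-hazards fit (Breslow partial likelihood)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson (convergence
#' when the score norm drops below `tol`, at most `max_iter` iterations).
#' Reports per-unit log-hazards with Wald standard errors, hazard ratios
#' with 95% confidence intervals and two-sided Wald p values. Monotone
#' likelihood (separation) is flagged via `converged = FALSE` when any
#' coefficient exceeds 20 in absolute value. Efron tie handling is available
#' behind the `ties` flag.
#'
#' @param X numeric matrix (or vector) of covariates, no missing values.
#' @param time follow-up times.
#' @param event event indicators (0/1), at least one event.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol score-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `cox_fit`: list with `beta`, `se`, `hr`, `ci95`
#'   (matrix lo/hi), `p`, `loglik`, `n`, `events`, `converged`, `iter`,
#'   `diagnostic`.
#' @export
cox_fit <- function(X, time, event, ties = c("breslow", "efron"),
                    tol = 1e-9, max_iter = 50L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X) || anyNA(time) || anyNA(event))
    stop("missing values in the model data", call. = FALSE)
  event <- as.integer(event != 0)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event) == 0L) stop("no events", call. = FALSE)
  ord <- order(time)
  X <- X[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  beta <- numeric(p)
  diagnostic <- NULL
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    sc <- cox_score_info(beta, X, time, event, ties)
    if (!all(is.finite(sc$score)) || !all(is.finite(sc$info))) {
      diagnostic <- "non-finite score (likely separation)"
      break
    }
    if (any(abs(beta) > 20)) {
      diagnostic <- "separation suspected: |beta| > 20"
      break
    }
    step <- tryCatch(solve(sc$info, sc$score), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      diagnostic <- "singular information matrix"
      break
    }
    beta <- beta + step
    scn <- cox_score_info(beta, X, time, event, ties)$score
    if (all(is.finite(scn)) && sqrt(sum(scn^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (any(!is.finite(beta) | abs(beta) > 20)) {
    converged <- FALSE
    diagnostic <- "separation suspected: |beta| > 20"
  }
  final <- cox_score_info(beta, X, time, event, ties)
  vcov <- tryCatch(solve(final$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  z <- beta / se
  ci <- cbind(lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se))
  rownames(ci) <- colnames(X)
  structure(list(beta = beta, se = se, hr = exp(beta), ci95 = ci,
                 p = 2 * stats::pnorm(-abs(z)), loglik = final$loglik,
                 n = n, events = sum(event), converged = converged,
                 iter = iter, ties = ties, diagnostic = diagnostic),
            class = "cox_fit")
}

# score, information and log partial likelihood at beta (data sorted by time)
cox_score_info <- function(beta, X, time, event, ties = "breslow") {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  # reverse cumulative risk-set sums, tied times share the full risk set
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(X * w, 2, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, n, p)
  # S2 upper-triangle cumulants
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  S2 <- sapply(seq_len(nrow(pairs)), function(k) {
    rev(cumsum(rev(w * X[, pairs[k, 1]] * X[, pairs[k, 2]])))
  })
  S2 <- matrix(S2, n, nrow(pairs))
  first_at <- match(time, time)  # index of first row with each time value
  score <- numeric(p); info <- matrix(0, p, p); loglik <- 0
  ev_idx <- which(event == 1L)
  # group events by tied time
  for (t0 in unique(time[ev_idx])) {
    ids <- ev_idx[time[ev_idx] == t0]
    d <- length(ids)
    i0 <- first_at[ids[1L]]
    xs <- colSums(X[ids, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      s0 <- S0[i0]; s1 <- S1[i0, ]; s2v <- S2[i0, ]
      loglik <- loglik + sum(eta[ids]) - d * log(s0)
      score <- score + xs - d * s1 / s0
      m2 <- matrix(0, p, p)
      m2[upper.tri(m2, diag = TRUE)] <- s2v
      m2 <- m2 + t(m2) - diag(diag(m2), p)
      info <- info + d * (m2 / s0 - tcrossprod(s1 / s0))
    } else {
      # Efron: subtract a growing fraction of the tied-event mass
      wd <- sum(w[ids]); s1d <- colSums(X[ids, , drop = FALSE] * w[ids])
      s2d <- numeric(nrow(pairs))
      for (k in seq_len(nrow(pairs)))
        s2d[k] <- sum(w[ids] * X[ids, pairs[k, 1]] * X[ids, pairs[k, 2]])
      loglik <- loglik + sum(eta[ids])
      for (r in seq_len(d) - 1L) {
        f <- r / d
        s0 <- S0[i0] - f * wd
        s1 <- S1[i0, ] - f * s1d
        s2v <- S2[i0, ] - f * s2d
        loglik <- loglik - log(s0)
        score <- score + xs / d - s1 / s0
        m2 <- matrix(0, p, p)
        m2[upper.tri(m2, diag = TRUE)] <- s2v
        m2 <- m2 + t(m2) - diag(diag(m2), p)
        info <- info + m2 / s0 - tcrossprod(s1 / s0)
      }
    }
  }
  list(score = score, info = info, loglik = loglik)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), n = %d, events = %d%s\n",
              x$ties, x$n, x$events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    lo95 = x$ci95[, "lo"], hi95 = x$ci95[, "hi"], p = x$p)
  print(round(tab, 4))
  if (!is.null(x$diagnostic)) cat("note:", x$diagnostic, "\n")
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$beta

#' Multivariable linear model for a standardized marker
#'
#' Ordinary least squares of a (standardized) HRV marker on a covariate set,
#' with Wald t-based 95% confidence intervals. The design must be full rank;
#' collinear columns are reported by name.
#'
#' @param y response (standardized marker values).
#' @param X covariate matrix or data.frame (an intercept is added).
#' @return object of class `linear_fit`: list with `beta`, `se`, `ci95`,
#'   `p`, `sigma`, `n`, `df_residual`.
#' @export
linear_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= ncol(X) + 1L)
    stop("need n > p + 1 observations", call. = FALSE)
  d <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(d)
  if (qrd$rank < ncol(d)) {
    dropped <- colnames(d)[qrd$pivot[(qrd$rank + 1L):ncol(d)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(d, y)
  df <- length(y) - ncol(d)
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(d)
  beta <- fit$coefficients
  tq <- stats::qt(0.975, df)
  ci <- cbind(lo = beta - tq * se, hi = beta + tq * se)
  p <- 2 * stats::pt(-abs(beta / se), df)
  structure(list(beta = beta, se = se, ci95 = ci, p = p,
                 sigma = sqrt(sigma2), n = length(y), df_residual = df),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear model, n = %d, residual SD = %.4g\n", x$n, x$sigma))
  print(round(data.frame(beta = x$beta, se = x$se, lo95 = x$ci95[, "lo"],
                         hi95 = x$ci95[, "hi"], p = x$p), 4))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) object$beta

#' Cumulative incidence (one minus Kaplan-Meier) per group
#'
#' @param time follow-up times.
#' @param event event indicators (0/1).
#' @param group group labels (factor or vector); empty levels are dropped
#'   with a warning.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `cuminc` (step-function coordinates; `cuminc = 1 - KM`).
#' @export
cumulative_incidence <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  empty <- levels(group)[tabulate(group, nbins = nlevels(group)) == 0L]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, cuminc = 1 - fit$surv,
             stringsAsFactors = FALSE)
}

#' Adjustment set for the model batteries
#'
#' @param tier `"age_sex"` or `"full"`.
#' @param covariates extra covariate column names for the full tier (risk
#'   factors, comorbidities, medication flags); ignored for `"age_sex"`.
#' @return object of class `adjustment_set`: character covariate names with
#'   age and sex always present.
#' @export
adjustment_set <- function(tier = c("age_sex", "full"),
                           covariates = character()) {
  tier <- match.arg(tier)
  covs <- if (tier == "age_sex") c("age", "sex")
          else unique(c("age", "sex", covariates))
  structure(list(tier = tier, covariates = covs), class = "adjustment_set")
}

#' Standardized Cox battery over a marker table
#'
#' Fits one Cox model per marker: the marker (divided by its sample SD in
#' the modelled sample, so hazard ratios are per SD) plus the adjustment
#' covariates. With `predictor = "out_of_range"` the marker is replaced by a
#' binary indicator of its value lying outside the supplied reference range.
#' Markers missing for more than half the subjects are skipped with a
#' warning; fits use complete cases per marker.
#'
#' @param markers data.frame of marker values (one row per subject).
#' @param cohort data.frame with the adjustment covariates and outcome
#'   columns `time` and `event` (override names via `time_col`/`event_col`).
#' @param adjustment an [adjustment_set].
#' @param predictor `"continuous"` (per-SD) or `"out_of_range"` (binary).
#' @param ranges named list of `reference_range` objects, required for
#'   `predictor = "out_of_range"`.
#' @param time_col,event_col outcome column names in `cohort`.
#' @param ties tie handling passed to [cox_fit].
#' @return data.frame with one row per marker: `marker`, `tier`,
#'   `predictor`, `hr`, `lo`, `hi`, `p`, `beta`, `se`, `n`, `events`,
#'   `converged`, and `sd` (the standardization divisor; `NA` for the
#'   binary predictor).
#' @export
run_model_battery <- function(markers, cohort, adjustment = adjustment_set(),
                              predictor = c("continuous", "out_of_range"),
                              ranges = NULL, time_col = "time",
                              event_col = "event",
                              ties = c("breslow", "efron")) {
  predictor <- match.arg(predictor)
  ties <- match.arg(ties)
  stopifnot(inherits(adjustment, "adjustment_set"),
            nrow(markers) == nrow(cohort))
  miss <- setdiff(c(adjustment$covariates, time_col, event_col),
                  names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (predictor == "out_of_range" && is.null(ranges))
    stop("reference ranges required for the out-of-range predictor",
         call. = FALSE)
  adj <- as.matrix(cohort[, adjustment$covariates, drop = FALSE])
  rows <- lapply(names(markers), function(mk) {
    v <- markers[[mk]]
    if (mean(is.na(v)) > 0.5) {
      warning("marker '", mk, "' missing for > 50% of subjects; skipped")
      return(NULL)
    }
    ok <- !is.na(v) & stats::complete.cases(adj) &
      !is.na(cohort[[time_col]]) & !is.na(cohort[[event_col]])
    sdv <- NA_real_
    x <- if (predictor == "continuous") {
      sdv <- stats::sd(v[ok])
      if (is.na(sdv) || sdv == 0) {
        warning("marker '", mk, "' has zero SD; skipped")
        return(NULL)
      }
      v[ok] / sdv
    } else {
      rg <- ranges[[mk]]
      if (is.null(rg)) {
        warning("no reference range for marker '", mk, "'; skipped")
        return(NULL)
      }
      as.numeric(classify_against_range(v[ok], rg) != "inside")
    }
    Xm <- cbind(marker = x, adj[ok, , drop = FALSE])
    fit <- cox_fit(Xm, cohort[[time_col]][ok], cohort[[event_col]][ok],
                   ties = ties)
    data.frame(marker = mk, tier = adjustment$tier, predictor = predictor,
               hr = fit$hr[["marker"]], lo = fit$ci95["marker", "lo"],
               hi = fit$ci95["marker", "hi"], p = fit$p[["marker"]],
               beta = fit$beta[["marker"]], se = fit$se[["marker"]],
               n = fit$n, events = fit$events, converged = fit$converged,
               sd = sdv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
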
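# Brute-force reference implementations used as independent oracles.
# These are deliberately naive (explicit loops, O(n^2)) and must stay
# independent of the package code paths they check.

tg_of <- function(values, rate = 4, start_time = 0) {
  structure(list(values = values, rate = rate, start_time = start_time),
            class = "tachogram")
}

nn_of <- function(intervals, id = "t") {
  nn_series(intervals, cumsum(intervals) / 1000, record_id = id)
}

# sample entropy template counts by double loop (Richman-Moorman)
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# correlation sums by double loop, Chebyshev metric, Theiler exclusion
oracle_corr_sums <- function(x, m, lag, radii, theiler) {
  np <- length(x) - (m - 1) * lag
  emb <- sapply(seq_len(m) - 1, function(k) x[(1:np) + k * lag])
  emb <- matrix(emb, np, m)
  counts <- numeric(length(radii)); npairs <- 0
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      if (j - i <= theiler) next
      npairs <- npairs + 1
      d <- max(abs(emb[i, ] - emb[j, ]))
      counts <- counts + (d <= radii)
    }
  }
  counts / npairs
}

# PRSA capacity by direct anchor evaluation
oracle_prsa <- function(x, direction, L = 2, max_rel = 0.05) {
  anchors <- c()
  for (i in 2:length(x)) {
    up <- x[i] > x[i - 1]
    ok <- if (direction == "deceleration") up else x[i] < x[i - 1]
    if (ok && abs(x[i] - x[i - 1]) <= max_rel * x[i - 1] &&
        i - L >= 1 && i + L - 1 <= length(x))
      anchors <- c(anchors, i)
  }
  if (!length(anchors)) return(NA_real_)
  X <- function(k) mean(x[anchors + k])
  (X(0) + X(1) - X(-1) - X(-2)) / 4
}

# two-sample log-rank statistic from the textbook risk-table formula
oracle_logrank <- function(time, event, group1) {
  ut <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t0 in ut) {
    at_risk <- time >= t0
    nt <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group1)
    OmE <- OmE + d1 - d * n1 / nt
    if (nt > 1) V <- V + d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1)
  }
  if (V <= 0) return(0)
  OmE / sqrt(V)
}

# Breslow log partial likelihood by explicit risk-set sums
oracle_breslow_loglik <- function(beta, X, time, event) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# product-limit (Kaplan-Meier) estimate by hand at given times
oracle_km <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- sapply(at, function(t0) {
    s <- 1
    for (tu in ut[ut <= t0]) {
      n <- sum(time >= tu)
      d <- sum(time == tu & event == 1)
      s <- s * (1 - d / n)
    }
    s
  })
  surv
}

# MODWT detail coefficients by direct circular convolution with the
# level-j equivalent wavelet filter (upsample-and-convolve construction)
oracle_modwt <- function(x, J) {
  f <- hrvcohort:::modwt_filters("la8")
  n <- length(x)
  upsample <- function(h, s) {
    z <- numeric((length(h) - 1) * s + 1)
    z[seq(1, length(z), by = s)] <- h
    z
  }
  out <- matrix(0, n, J)
  g_prev <- 1
  for (j in seq_len(J)) {
    hj <- convolve(upsample(f$h, 2^(j - 1)), rev(g_prev), type = "open")
    for (t in seq_len(n)) {
      idx <- ((t - 1) - (seq_along(hj) - 1)) %% n + 1
      out[t, j] <- sum(hj * x[idx])
    }
    g_prev <- convolve(upsample(f$g, 2^(j - 1)), rev(g_prev), type = "open")
  }
  out
}
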
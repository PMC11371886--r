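test_that("standardization divides by the sample SD without centering", {
  out <- standardize_columns(cbind(a = c(2, 4, 6)))
  expect_equal(out$z[, "a"], c(1, 2, 3))
  expect_equal(out$sd[["a"]], 2)

  unit <- cbind(u = rnorm(50))
  unit[, 1] <- unit[, 1] / sd(unit[, 1])
  expect_equal(standardize_columns(unit)$z[, "u"], unit[, "u"],
               tolerance = 1e-12)
  expect_error(standardize_columns(cbind(ok = 1:5, flat = rep(3, 5))),
               "flat")
})

test_that("Cox toy problem has the closed-form solution -log(2)/2", {
  fit <- cox_fit(matrix(c(1, 0, 1), 3, 1), time = c(1, 2, 3),
                 event = c(1, 1, 1))
  expect_equal(unname(fit$beta), -0.5 * log(2), tolerance = 1e-8)
  expect_equal(unname(fit$hr), 1 / sqrt(2), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("Cox estimates maximize the partial likelihood (grid oracle)", {
  set.seed(111)
  for (i in 1:4) {
    n <- 6
    x <- rnorm(n)
    time <- sample(seq(0.5, 3, by = 0.5))   # distinct times
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1
    fit <- cox_fit(matrix(x), time, event)
    grid <- seq(-5, 5, by = 1e-4)
    ll <- vapply(grid, function(b)
      oracle_breslow_loglik(b, matrix(x), time, event), numeric(1))
    b_star <- grid[which.max(ll)]
    if (abs(b_star) < 4.9) {   # interior maximum (no separation)
      expect_equal(unname(fit$beta), b_star, tolerance = 1e-3)
    }
  }
})

test_that("Breslow partial likelihood equals the naive risk-set oracle", {
  set.seed(112)
  n <- 80
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  time <- round(rexp(n), 1) + 0.1     # induces ties
  event <- rbinom(n, 1, 0.6)
  fit <- cox_fit(X, time, event)
  expect_equal(fit$loglik,
               oracle_breslow_loglik(fit$beta, X, time, event),
               tolerance = 1e-8)
})

test_that("Cox fits agree with survival::coxph in both tie conventions", {
  set.seed(113)
  n <- 150
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  time <- round(rexp(n, exp(0.4 * X[, "a"])), 1) + 0.1
  event <- rbinom(n, 1, 0.7)
  for (tie in c("breslow", "efron")) {
    fit <- cox_fit(X, time, event, ties = tie)
    ref <- survival::coxph(survival::Surv(time, event) ~ X, ties = tie)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-7)
  }
})

test_that("per-SD hazard ratios are equivariant to rescaling", {
  set.seed(114)
  n <- 200
  x <- rnorm(n, sd = 37)
  time <- rexp(n, exp(0.01 * x)); event <- rbinom(n, 1, 0.8)
  raw <- cox_fit(matrix(x), time, event)
  std <- cox_fit(matrix(x / sd(x)), time, event)
  expect_equal(unname(raw$beta) * sd(x), unname(std$beta),
               tolerance = 1e-8)
})

test_that("separation and zero-information cases are flagged, not reported", {
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- rep(c(1, 0), each = 4)      # perfect separation
  fit <- cox_fit(matrix(x), time, event)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|singular|non-finite")
})

test_that("linear fits reproduce exact and oracle solutions", {
  x <- rnorm(30)
  f <- linear_fit(2 * x, cbind(x = x))
  expect_equal(unname(f$beta[["x"]]), 2, tolerance = 1e-10)
  expect_lt(f$sigma, 1e-10)

  set.seed(115)
  n <- 1e4
  X <- cbind(x = rnorm(n))
  y <- rnorm(n)
  f2 <- linear_fit(y, X)
  expect_lt(abs(f2$beta[["x"]]), 3 * f2$se[["x"]])

  # normal-equations oracle
  set.seed(116)
  X3 <- cbind(a = rnorm(40), b = runif(40))
  y3 <- 1 + X3 %*% c(0.5, -2) + rnorm(40, 0, 0.3)
  f3 <- linear_fit(drop(y3), X3)
  D <- cbind(1, X3)
  beta_o <- solve(t(D) %*% D, t(D) %*% y3)
  expect_equal(unname(f3$beta), unname(drop(beta_o)), tolerance = 1e-10)

  expect_error(linear_fit(rnorm(20), cbind(a = 1:20, b = 2 * (1:20))),
               "collinear")
})

test_that("cumulative incidence equals hand product-limit arithmetic", {
  # no events: flat zero
  ci0 <- cumulative_incidence(1:5, rep(0, 5))
  expect_true(all(ci0$cuminc == 0))

  # all die at distinct times: 1/n steps reaching 1
  ci1 <- cumulative_incidence(1:5, rep(1, 5))
  expect_equal(ci1$cuminc, (1:5) / 5)

  # 6-subject toy with censoring before the first event
  time <- c(0.5, 0.7, 1, 2, 2, 3)
  event <- c(0, 0, 1, 1, 0, 1)
  ci2 <- cumulative_incidence(time, event)
  at <- sort(unique(time))
  expect_equal(1 - ci2$cuminc[match(c(1, 2, 3), ci2$time)],
               oracle_km(time, event, c(1, 2, 3)), tolerance = 1e-12)

  # no censoring: 1 - KM is exactly the empirical CDF
  set.seed(117)
  tt <- rexp(40)
  ci3 <- cumulative_incidence(tt, rep(1, 40))
  expect_equal(ci3$cuminc[match(sort(tt), ci3$time)],
               ecdf(tt)(sort(tt)), tolerance = 1e-12)

  expect_warning(
    cumulative_incidence(1:4, c(1, 1, 0, 0),
                         factor(c("a", "a", "a", "a"),
                                levels = c("a", "b"))), "empty")
})

test_that("model battery recovers generator hazard ratios", {
  set.seed(118)
  co <- gen_cohort(cohort_gen_params(1000, betas = c(dc = -0.36),
                                     seed = 119))
  cohort <- co$covariates
  cohort$time <- cohort$time_years
  bt <- run_model_battery(co$markers, cohort, adjustment_set("age_sex"),
                          time_col = "time", event_col = "event")
  r <- bt[bt$marker == "dc", ]
  expect_true(r$lo <= exp(-0.36) && exp(-0.36) <= r$hi)
  expect_equal(r$hr, exp(-0.36), tolerance = 0.15)
})

test_that("battery supports the binary out-of-range predictor", {
  set.seed(120)
  n <- 2000
  z <- rnorm(n)
  rg <- structure(list(marker = "m", lower = qnorm(0.05),
                       upper = qnorm(0.95), lower_p = 0.05, upper_p = 0.95,
                       n_reference = n, convention = "linear"),
                  class = "reference_range")
  outside <- z < rg$lower | z > rg$upper
  t_event <- rexp(n, 0.05 * ifelse(outside, 2, 1))   # doubled hazard outside
  event <- as.integer(t_event <= 8)
  time <- pmin(t_event, 8)
  cohort <- data.frame(age = rnorm(n, 65, 10), sex = rbinom(n, 1, 0.4),
                       time = time, event = event)
  bt <- run_model_battery(data.frame(m = z), cohort,
                          adjustment_set("age_sex"),
                          predictor = "out_of_range", ranges = list(m = rg))
  expect_equal(bt$hr, 2, tolerance = 0.2)
  expect_true(bt$lo <= 2 && 2 <= bt$hi)
})

test_that("markers mostly missing are skipped with a warning", {
  set.seed(121)
  n <- 60
  mk <- data.frame(good = rnorm(n), bad = c(rnorm(10), rep(NA, n - 10)))
  cohort <- data.frame(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
                       time = rexp(n), event = rbinom(n, 1, 0.6))
  cohort$event[1] <- 1
  expect_warning(bt <- run_model_battery(mk, cohort,
                                         adjustment_set("age_sex")),
                 "bad")
  expect_equal(bt$marker, "good")
})
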
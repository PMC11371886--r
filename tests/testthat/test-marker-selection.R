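test_that("literature ranking sorts by hits with deterministic tie breaks", {
  tab <- data.frame(marker = c("sdnn", "lf", "dc"),
                    hit_count = c(500, 300, 10))
  expect_equal(rank_by_hits(tab, 2), c("sdnn", "lf"))
  expect_equal(rank_by_hits(data.frame(marker = c("b", "a"),
                                       hit_count = c(5, 5)), 1), "a")
  full <- rank_by_hits(tab, 3)
  expect_setequal(full, tab$marker)
  expect_error(rank_by_hits(tab, 4), "exceeds")
  expect_error(rank_by_hits(data.frame(marker = c("a", "a"),
                                       hit_count = c(1, 2)), 1), "duplicate")
})

test_that("top-union selection handles overlap correctly", {
  lit <- paste0("L", 1:10)
  for_ <- paste0("F", 1:10)
  expect_equal(nrow(select_top_union(lit, for_, 10)), 20)
  expect_equal(nrow(select_top_union(lit, lit, 10)), 10)
  one_over <- c("L1", paste0("F", 2:10))
  sel <- select_top_union(lit, one_over, 10)
  expect_equal(nrow(sel), 19)
  expect_equal(sel$source[sel$marker == "L1"], "both")
  expect_error(select_top_union(lit[1:5], for_, 10), "exceeds")
})

test_that("log-rank split statistic equals the textbook oracle", {
  set.seed(101)
  for (rep_i in 1:5) {
    n <- 40
    time <- round(rexp(n), 1) + 0.1
    event <- rbinom(n, 1, 0.6)
    x <- rnorm(n)
    ord <- order(time)
    cuts <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    st <- hrvcohort:::cpp_logrank_stats(time[ord], as.integer(event[ord]),
                                        x[ord], cuts)
    for (k in seq_along(cuts)) {
      expect_equal(st[k], oracle_logrank(time, event, x <= cuts[k]),
                   tolerance = 1e-10)
    }
  }
})

test_that("a perfectly separating binary column is chosen at the root", {
  # early deaths all have x = 1, late censorings x = 0
  X <- cbind(flag = rep(c(1, 0), each = 4), noise = rep(0.5, 8))
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fo <- fit_survival_forest(X, time, event,
                            forest_params(n_trees = 5, mtry = 2,
                                          min_node_size = 2,
                                          min_node_deaths = 1, seed = 1))
  roots <- vapply(fo$trees, function(tr) tr$split_var[tr$id == 1], "")
  expect_true(all(roots == "flag"))
})

test_that("forests are deterministic given a seed and bootstrap has size n", {
  set.seed(102)
  X <- matrix(rnorm(60 * 3), 60, dimnames = list(NULL, c("a", "b", "c")))
  time <- rexp(60); event <- rbinom(60, 1, 0.5)
  event[1] <- 1
  f1 <- fit_survival_forest(X, time, event,
                            forest_params(n_trees = 10, seed = 7))
  f2 <- fit_survival_forest(X, time, event,
                            forest_params(n_trees = 10, seed = 7))
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$in_bag, f2$in_bag)
  expect_true(all(vapply(f1$in_bag, length, 1L) == 60))
  expect_true(any(vapply(f1$in_bag, anyDuplicated, 1L) > 0))
})

test_that("minimal depth conventions: root split 0, absent = max depth", {
  X <- cbind(flag = rep(c(1, 0), each = 4), noise = rep(0.5, 8))
  time <- c(1, 2, 3, 4, 10, 11, 12, 13)
  event <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fo <- fit_survival_forest(X, time, event,
                            forest_params(n_trees = 3, mtry = 2,
                                          min_node_size = 2,
                                          min_node_deaths = 1, seed = 2))
  md <- minimal_depth_importance(fo)
  expect_equal(md[["flag"]], 0)
  worst <- mean(vapply(fo$trees, function(tr)
    max(tr$depth[is.na(tr$split_var)]), numeric(1)))
  expect_equal(md[["noise"]], worst)  # constant column is never split on
})

test_that("forest structure is invariant under monotone predictor transforms", {
  set.seed(103)
  n <- 80
  X <- cbind(a = rnorm(n), b = runif(n))
  time <- rexp(n, exp(0.8 * X[, "a"]))
  event <- rbinom(n, 1, 0.8)
  f1 <- fit_survival_forest(X, time, event,
                            forest_params(n_trees = 10, mtry = 2, seed = 4,
                                          min_node_size = 10,
                                          min_node_deaths = 2))
  X2 <- X
  X2[, "a"] <- exp(X[, "a"])        # strictly monotone transform
  f2 <- fit_survival_forest(X2, time, event,
                            forest_params(n_trees = 10, mtry = 2, seed = 4,
                                          min_node_size = 10,
                                          min_node_deaths = 2))
  # same topology: split variables and depths agree tree by tree
  for (b in seq_along(f1$trees)) {
    expect_identical(f1$trees[[b]]$split_var, f2$trees[[b]]$split_var)
    expect_identical(f1$trees[[b]]$depth, f2$trees[[b]]$depth)
    expect_identical(f1$trees[[b]]$n, f2$trees[[b]]$n)
  }
  expect_identical(minimal_depth_importance(f1),
                   minimal_depth_importance(f2))
})

test_that("minimal depth ranks a hazard-driving marker above noise", {
  set.seed(104)
  co <- gen_cohort(cohort_gen_params(300, betas = c(driver = 1),
                                     marker_names = c("driver", paste0("n", 1:4)),
                                     seed = 105))
  X <- cbind(as.matrix(co$markers), age = co$covariates$age,
             sex = co$covariates$sex)
  fo <- fit_survival_forest(X, co$covariates$time_years,
                            co$covariates$event,
                            forest_params(n_trees = 50, seed = 106),
                            forced = c("age", "sex"))
  md <- minimal_depth_importance(fo)
  noise <- paste0("n", 1:4)
  expect_lt(md[["driver"]], min(md[noise]))
})

test_that("forest refuses degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_survival_forest(X, rexp(10), rep(0, 10)), "no events")
  X[1, 1] <- NA
  expect_error(fit_survival_forest(X, rexp(10), rep(1, 10)), "missing")
})
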
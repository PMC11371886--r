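test_that("read_rr_text parses both dialects and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("800", "810", "790"), f)
  rr <- read_rr_text(f)
  expect_equal(rr$intervals, c(800, 810, 790))
  expect_equal(rr$beat_times, c(0.8, 1.61, 2.4))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,rr_ms", "0.8,800", "1.61,810"), f2)
  rr2 <- read_rr_text(f2, dialect = "time_interval_csv")
  expect_equal(rr2$intervals, c(800, 810))
  expect_equal(rr2$beat_times, c(0.8, 1.61))

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("800", "abc"), f3)
  expect_error(read_rr_text(f3), "line 2")

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f4)
  expect_error(read_rr_text(f4), "empty")
})

test_that("round trip through write_rr_text preserves the series", {
  nn <- nn_of(c(812.25, 790, 805.5))
  f <- withr::local_tempfile(fileext = ".txt")
  write_rr_text(nn, f)
  expect_equal(read_rr_text(f)$intervals, nn$intervals)
})

test_that("eligibility applies pacemaker, AF-fraction and transplant rules", {
  expect_true(check_eligibility(record_meta("a"))$included)
  d <- check_eligibility(record_meta("b", af_fraction = 0.5))
  expect_false(d$included)
  expect_equal(d$reason, "af")
  expect_true(check_eligibility(record_meta("c",
                                            af_fraction = 0.49))$included)
  d2 <- check_eligibility(record_meta("d", af_fraction = 0.49,
                                      has_pacemaker = TRUE))
  expect_equal(d2$reason, "pacemaker")
  expect_equal(check_eligibility(record_meta("e",
                                             heart_transplant = TRUE))$reason,
               "transplant")
  expect_error(record_meta("f", af_fraction = 1.2), "af_fraction")
})

test_that("eligibility is a pure per-record function (permutation property)", {
  set.seed(42)
  metas <- lapply(1:30, function(i)
    record_meta(i, has_pacemaker = runif(1) < 0.2,
                af_fraction = runif(1),
                heart_transplant = runif(1) < 0.1))
  dec <- vapply(metas, function(m) check_eligibility(m)$reason, "")
  perm <- sample(30)
  dec_perm <- vapply(metas[perm], function(m) check_eligibility(m)$reason, "")
  expect_identical(dec_perm, dec[perm])
})

test_that("artifact filter applies bounds and running-median rules", {
  clean <- rr_series(rep(800, 100))
  nn <- filter_to_nn(clean)
  expect_equal(nn$rejected_count, 0L)
  expect_length(nn$intervals, 100)

  spike_low <- rr_series(c(rep(800, 50), 150, rep(800, 50)))
  nn2 <- filter_to_nn(spike_low)
  expect_equal(nn2$rejected_count, 1L)
  expect_length(nn2$intervals, 100)
  expect_false(150 %in% nn2$intervals)

  spike_rel <- rr_series(c(rep(800, 50), 1100, rep(800, 50)))
  nn3 <- filter_to_nn(spike_rel)   # |1100-800|/800 = 0.375 > 0.2
  expect_equal(nn3$rejected_count, 1L)

  labelled <- rr_series(rep(800, 10),
                        labels = c(rep("normal", 5), "ectopic",
                                   rep("normal", 4)))
  expect_equal(filter_to_nn(labelled)$rejected_count, 1L)

  expect_error(filter_to_nn(rr_series(rep(100, 5))), "all beats rejected")
})

test_that("artifact filter is idempotent", {
  set.seed(11)
  x <- 800 + cumsum(rnorm(500, 0, 8))
  x[c(50, 200, 355)] <- c(150, 1400, 2500)
  nn1 <- filter_to_nn(rr_series(x))
  rr2 <- rr_series(nn1$intervals, nn1$beat_times)
  nn2 <- filter_to_nn(rr2)
  expect_equal(nn2$rejected_count, 0L)
  expect_equal(nn2$intervals, nn1$intervals)
})

test_that("tachogram resampling interpolates on a uniform grid", {
  const <- nn_of(rep(800, 20))
  tg <- resample_tachogram(const, rate = 4)
  expect_true(all(abs(tg$values - 800) < 1e-9))

  two <- nn_series(c(800, 900), c(1, 1.9))
  tg2 <- resample_tachogram(two, rate = 4, method = "linear")
  slope <- diff(tg2$values) / 0.25
  expect_true(all(abs(slope - slope[1]) < 1e-9))   # linear between beats
  expect_equal(tg2$values[1], 800)

  expect_error(resample_tachogram(nn_series(800, 0.8)), "2 beats")
})

test_that("resampled sinusoidal modulation keeps its dominant frequency", {
  f_mod <- 0.1
  t <- 0; ints <- c()
  while (t < 600) {
    v <- 800 + 50 * sin(2 * pi * f_mod * t)
    ints <- c(ints, v); t <- t + v / 1000
  }
  nn <- nn_of(ints)
  tg <- resample_tachogram(nn, rate = 4)
  x <- tg$values - mean(tg$values)
  sp <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * tg$rate / length(x)
  half <- freqs <= tg$rate / 2 & freqs > 0
  expect_equal(freqs[half][which.max(sp[half])], f_mod, tolerance = 0.01)
})

test_that("tachogram mean approximates the time-weighted interval mean", {
  set.seed(5)
  x <- 800 + cumsum(rnorm(400, 0, 5))
  nn <- nn_of(x)
  tg <- resample_tachogram(nn, rate = 4)
  tw <- sum(x * x / 1000) / sum(x / 1000)   # time-weighted mean
  expect_equal(mean(tg$values), tw, tolerance = 0.005)
})
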
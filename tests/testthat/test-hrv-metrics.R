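# Time-domain HRV metrics and distribution characterization.

test_that("heart rate is 60 over the mean interval", {
  expect_equal(heart_rate(rep(0.2, 7)), 300)
  expect_equal(heart_rate(rep(1.0, 3)), 60)
  expect_equal(heart_rate(c(0.15, 0.25)), 300)
  expect_error(heart_rate(numeric(0)), "empty")
})

test_that("SDNN closed forms and preconditions", {
  expect_equal(sdnn(rep(0.21, 5)), 0)
  expect_equal(sdnn(c(0.2, 0.3)), sqrt(0.005))
  expect_error(sdnn(0.2), ">= 2")
})

test_that("RMSSD closed forms and brute-force oracle equality", {
  expect_equal(rmssd(rep(0.21, 5)), 0)
  expect_equal(rmssd(c(0.2, 0.3, 0.2, 0.3)), 0.1)
  expect_error(rmssd(0.2), ">= 2")
  set.seed(31)
  for (rep in 1:20) {
    x <- runif(sample(2:400, 1), 0.1, 0.3)
    expect_equal(rmssd(x), brute_rmssd(x), tolerance = 1e-12)
    expect_equal(sdnn(x), brute_sdnn(x), tolerance = 1e-12)
  }
})

test_that("moments use biased central moments and the non-excess convention", {
  m <- distribution_moments(c(1, 2, 3, 2))
  expect_equal(m$mean, 2)
  # hand-checked three-point symmetric case
  m3 <- distribution_moments(c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  expect_equal(m3$skewness, 0)
  expect_equal(m3$kurtosis, (2 / 3) / (4 / 9) ^ 2 * (4 / 9), tolerance = 1e-12)
  expect_equal(m3$kurtosis, 1.5)
})

test_that("degenerate zero-variance input is flagged, not fabricated", {
  m <- distribution_moments(rep(0.2, 10))
  expect_true(isTRUE(attr(m, "degenerate")))
  expect_true(is.na(m$skewness) && is.na(m$kurtosis))
})

test_that("histogram bins conserve counts and span the range", {
  h <- rr_histogram(c(0.1, 0.1, 0.2), 2)
  expect_identical(h$counts, c(2L, 1L))
  set.seed(5)
  x <- runif(500, 0.1, 0.25)
  h2 <- rr_histogram(x, 13)
  expect_identical(sum(h2$counts), 500L)
  expect_error(rr_histogram(x, 0), "n_bins")
})

test_that("sham-scenario sample stays within the printed histogram range", {
  # soft envelope check at the 0.5/99.5 percentile level
  x <- sample_dist(fit_scenario_row("sham"), 1e5, seed = 3)
  q <- quantile(x, c(0.005, 0.995))
  expect_gte(q[1], 0.12)
  expect_lte(q[2], 0.206)
})

test_that("SDNN/RMSSD are translation-invariant, HR is not", {
  set.seed(8)
  x <- runif(50, 0.15, 0.25)
  expect_equal(sdnn(x + 0.05), sdnn(x))
  expect_equal(rmssd(x + 0.05), rmssd(x))
  expect_false(isTRUE(all.equal(heart_rate(x + 0.05), heart_rate(x))))
})

test_that("time reversal leaves SDNN, RMSSD and all moments unchanged", {
  set.seed(9)
  x <- runif(101, 0.1, 0.3)
  expect_equal(sdnn(rev(x)), sdnn(x))
  expect_equal(rmssd(rev(x)), rmssd(x))
  expect_equal(unclass(distribution_moments(rev(x))),
               unclass(distribution_moments(x)))
})

test_that("RMSSD obeys the successive-difference bound", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(2:300, 1)
    x <- rnorm(n, 0.2, 0.05)
    expect_lte(rmssd(x), 2 * sdnn(x) * sqrt(n / (n - 1)) + 1e-12)
  }
})

test_that("for iid Gaussian R-R, RMSSD/sqrt(2) estimates SDNN", {
  set.seed(11)
  ratio <- replicate(30, {
    x <- rnorm(2000, 0.2, 0.01)
    rmssd(x) / sqrt(2) / sdnn(x)
  })
  expect_lt(abs(mean(ratio) - 1), 3 * sd(ratio) / sqrt(30))
  # and at large N the two agree closely in one sample
  x <- rnorm(1e5, 0.2, 0.01)
  expect_lt(abs(rmssd(x) / sqrt(2) - sdnn(x)) / sdnn(x), 0.02)
})

test_that("pooling emits one row per epoch and per-animal means", {
  p <- rr_process_params(0.2, 0.005)
  rows <- list()
  k <- 0
  for (a in 1:3) for (e in 1:8) {
    k <- k + 1
    rows[[k]] <- hrv_metrics(simulate_rr_series(
      p, 50, seed = k, animal_id = sprintf("r%d", a), group = "sham",
      epoch = e))
  }
  pooled <- pool_epochs(rows)
  expect_identical(nrow(pooled$per_epoch), 24L)
  expect_identical(nrow(pooled$per_animal), 3L)
  # eight identical epochs collapse to the epoch value
  one <- hrv_metrics(simulate_rr_series(p, 50, seed = 1,
                                        animal_id = "rX", group = "g",
                                        epoch = 1L))
  eight <- pool_epochs(do.call(rbind, replicate(8, one, simplify = FALSE)))
  expect_equal(eight$per_animal$hr_bpm, one$hr_bpm)
})
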
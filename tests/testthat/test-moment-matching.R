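# Johnson-system moment matching and sampling.

test_that("Gaussian target reproduces the normal distribution", {
  spec <- fit_moment_matched(moment_set(0, 1, 0, 3))
  expect_identical(spec$family, "sn")
  expect_lt(abs(spec$implied$skewness), 1e-6)
  expect_equal(spec$implied$mean, 0, tolerance = 1e-12)
  expect_equal(spec$implied$sd, 1, tolerance = 1e-12)
  x <- sample_dist(spec, 1e4, seed = 1)
  expect_equal(mean(x), 0, tolerance = 4 / sqrt(1e4))
})

test_that("lognormal moments round-trip through the fit (closed-form oracle)", {
  lm <- lognormal_moments(-1.9, 0.05)
  spec <- fit_moment_matched(moment_set(lm["mean"], lm["sd"],
                                        lm["skew"], lm["kurt"]))
  n <- 1e6
  x <- sample_dist(spec, n, seed = 11)
  m <- distribution_moments(x)
  expect_lt(abs(m$mean - lm["mean"]), 3 * lm["sd"] / sqrt(n))
  expect_lt(abs(m$sd - lm["sd"]), 3 * lm["sd"] / sqrt(2 * n))
  expect_lt(abs(m$skewness - lm["skew"]), 3 * batch_se(x, function(v)
    distribution_moments(v)$skewness))
  expect_lt(abs(m$kurtosis - lm["kurt"]), 3 * batch_se(x, function(v)
    distribution_moments(v)$kurtosis))
})

test_that("every scenario row is feasible and fits within tolerance", {
  for (nm in names(scenario_moments)) {
    r <- scenario_moments[[nm]]
    expect_gt(r[4], r[3]^2 + 1)  # moment feasibility
    spec <- fit_scenario_row(nm)
    expect_equal(spec$implied$mean, r[1], tolerance = 1e-9)
    expect_equal(spec$implied$sd, r[2], tolerance = 1e-9)
    expect_lt(abs(spec$implied$skewness - r[3]), 1e-3)
    expect_lt(abs(spec$implied$kurtosis - r[4]), 1e-3)
  }
})

test_that("boundary-adjacent and heavy-tailed rows select the expected families", {
  # sham sits 0.027 above the kurtosis feasibility bound -> bounded family
  expect_identical(fit_scenario_row("sham")$family, "sb")
  # the heavy-tailed propolis-lesion row is above the lognormal line
  expect_identical(fit_scenario_row("ohda_p")$family, "su")
})

test_that("infeasible moment combinations are rejected naming the bound", {
  expect_error(moment_set(0, 1, 2, 3), "skewness\\^2 \\+ 1")
  expect_error(fit_moment_matched(structure(
    list(mean = 0, sd = 1, skewness = 2, kurtosis = 3),
    class = "moment_set")), "skewness\\^2 \\+ 1")
})

test_that("zero-variance sampling is exactly constant", {
  spec <- fit_moment_matched(moment_set(0.2, 0, 0, 3))
  expect_identical(as.numeric(sample_dist(spec, 5, seed = 3)),
                   rep(0.2, 5))
})

test_that("draws are seed-reproducible and seed-independent in distribution", {
  spec <- fit_scenario_row("sham_p")
  x1 <- sample_dist(spec, 1e5, seed = 7)
  x2 <- sample_dist(spec, 1e5, seed = 7)
  expect_identical(as.numeric(x1), as.numeric(x2))
  y <- sample_dist(spec, 1e5, seed = 8)
  se_mean <- spec$implied$sd / sqrt(1e5)
  expect_lt(abs(mean(x1) - mean(y)), 6 * se_mean)
})

test_that("positivity clipping is applied and counted", {
  spec <- fit_scenario_row("ohda_p")  # unbounded left tail
  x <- sample_dist(spec, 1e6, seed = 7, clip_floor = 0.05)
  expect_gte(min(x), 0.05)
  expect_identical(attr(x, "n_clipped"), sum(x == 0.05))
  # bounded sham support lies inside the physiological range: no clips
  xs <- sample_dist(fit_scenario_row("sham"), 1e5, seed = 7,
                    clip_floor = 0.05)
  expect_identical(attr(xs, "n_clipped"), 0L)
  sup <- dist_support(fit_scenario_row("sham"))
  expect_gt(sup[1], 0.05)
})
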
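# Nonparametric group-comparison chain.

test_that("Kruskal-Wallis reproduces the hand-ranked instance H = 7.2", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_identical(kw$df, 2)
  expect_equal(kw$statistic, brute_kruskal(g), tolerance = 1e-12)
})

test_that("identical groups show no separation", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kw <- kruskal_wallis(g)
  expect_gt(kw$p_value, 0.9)
  all_same <- list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4))
  kw2 <- kruskal_wallis(all_same)
  expect_identical(kw2$statistic, 0)
  expect_identical(kw2$p_value, 1)
  pw <- bonferroni_posthoc(all_same)
  expect_true(all(pw$p_adj == 1))
})

test_that("H matches the brute-force rank formula on random small instances", {
  set.seed(21)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    g <- lapply(seq_len(k), function(i)
      sample(1:6, sample(2:4, 1), replace = TRUE))  # forces ties
    names(g) <- letters[seq_len(k)]
    if (length(unique(unlist(g))) == 1) next
    expect_equal(kruskal_wallis(g)$statistic, brute_kruskal(g),
                 tolerance = 1e-12)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(22)
  g <- list(a = runif(8), b = runif(6) + 0.2, c = runif(7) * 2)
  h0 <- kruskal_wallis(g)$statistic
  for (f in list(function(x) x^3, exp, function(x) 5 * x - 2)) {
    expect_equal(kruskal_wallis(lapply(g, f))$statistic, h0,
                 tolerance = 1e-12)
  }
})

test_that("Dunn-Bonferroni flags only the separated pair", {
  set.seed(23)
  g <- list(a = rnorm(40), b = rnorm(40) + 10, c = rnorm(40),
            d = rnorm(40) + 0.1)
  pw <- bonferroni_posthoc(g)
  sig <- pw[pw$significant, c("group1", "group2")]
  expect_true(all(sig$group1 == "b" | sig$group2 == "b"))
  expect_true(any(sig$group1 == "a" & sig$group2 == "b" |
                    sig$group1 == "b" & sig$group2 == "a"))
  expect_true(all(pw$p_adj >= pw$p_raw))
  expect_true(all(pw$p_adj <= 1))
})

test_that("notched box summary closed form", {
  b <- box_summary(c(1, 2, 3, 4, 5))
  expect_equal(b$median, 3)
  expect_equal(b$iqr, 2)
  expect_equal(b$notch_half, 1.57 * 2 / sqrt(5), tolerance = 1e-12)
  const <- box_summary(rep(4, 9))
  expect_equal(const$iqr, 0)
  expect_equal(const$notch_half, 0)
})

test_that("KS normality screen: degenerate input, cross-check, and power", {
  deg <- ks_normality(rep(1, 10))
  expect_true(deg$degenerate)
  expect_lt(deg$p_value, 1e-300)
  # cross-check the Monte-Carlo p against the analytic Lilliefors test
  set.seed(24)
  x <- rnorm(80, 3, 2)
  ours <- ks_normality(x, n_null = 4000, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_lt(abs(ours$p_value - ref$p.value), 0.05)
  # power: a clearly non-normal sample is rejected in nearly all trials
  tab <- ks_null_table(200, 2000, seed = 2)
  set.seed(25)
  rej <- mean(replicate(60, {
    ks_normality(rexp(200), null_stats = tab)$p_value < 0.05
  }))
  expect_gte(rej, 0.95)
})

test_that("KS normality screen has calibrated type-I error", {
  tab <- ks_null_table(60, 2000, seed = 3)
  set.seed(26)
  trials <- 500
  rej <- mean(replicate(trials, {
    ks_normality(rnorm(60), null_stats = tab)$p_value < 0.05
  }))
  band <- 3 * sqrt(0.05 * 0.95 / trials)
  expect_gte(rej, 0.05 - band)
  expect_lte(rej, 0.05 + band)
})

test_that("chain gates pairwise flags on the omnibus test", {
  set.seed(27)
  g <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5), d = rnorm(5))
  ch <- group_chain(g)
  if (ch$kw$p_value >= 0.05) expect_false(any(ch$pairwise$significant))
  g2 <- list(a = rnorm(20), b = rnorm(20) + 8,
             c = rnorm(20), d = rnorm(20))
  ch2 <- group_chain(g2)
  expect_true(any(ch2$pairwise$significant))
})
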
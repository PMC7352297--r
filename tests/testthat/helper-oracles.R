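# Independent brute-force oracles and shared fixtures. Oracles are kept
# deliberately naive (explicit loops, textbook formulas) so they stay
# independent of the vectorized implementation paths they check.

# The four-group R-R moment scenario driving the moment-matching suite:
# mean (s), sd (s), skewness, non-excess kurtosis.
scenario_moments <- list(
  sham   = c(0.1467, 0.0072,  1.5494,  3.4277),
  sham_p = c(0.1723, 0.0143, -0.9413,  4.9860),
  ohda   = c(0.2415, 0.1675,  1.0905,  3.3249),
  ohda_p = c(0.1889, 0.0080, -0.9608, 15.3378))

# Johnson fits are deterministic and expensive near the feasibility
# boundary; memoize per test run.
.fit_cache <- new.env(parent = emptyenv())
fit_scenario_row <- function(name) {
  if (is.null(.fit_cache[[name]])) {
    r <- scenario_moments[[name]]
    .fit_cache[[name]] <-
      fit_moment_matched(moment_set(r[1], r[2], r[3], r[4]))
  }
  .fit_cache[[name]]
}

# naive RMSSD: explicit loop over successive differences
brute_rmssd <- function(x) {
  acc <- 0
  for (i in seq_len(length(x) - 1)) acc <- acc + (x[i + 1] - x[i])^2
  sqrt(acc / (length(x) - 1))
}

# naive SDNN
brute_sdnn <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  sqrt(acc / (length(x) - 1))
}

# brute-force R-peak detection: enumerate super-threshold local maxima
# (window +/- win samples, plateau resolves to its first sample), then
# keep greedily by descending amplitude subject to the refractory gap.
brute_detect <- function(x, fs, threshold_factor = 0.7,
                         min_distance = 0.1) {
  thr <- mean(x) + threshold_factor * sd(x)
  win <- max(1L, round(0.010 * fs))
  n <- length(x)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (x[i] <= thr) next
    lo <- max(1L, i - win); hi <- min(n, i + win)
    if (any(x[lo:hi] > x[i])) next
    if (i > 1 && x[i - 1] == x[i]) next  # plateau continuation
    cand <- c(cand, i)
  }
  gap <- round(min_distance * fs)
  kept <- integer(0)
  for (j in order(-x[cand], cand)) {
    i <- cand[j]
    if (!length(kept) || all(abs(kept - i) >= gap)) kept <- c(kept, i)
  }
  sort(kept)
}

# textbook Kruskal-Wallis with midranks and tie correction
brute_kruskal <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), n)
  R <- vapply(seq_along(groups), function(i) sum(r[idx == i]), numeric(1))
  h <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  tt <- table(x)
  corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (corr == 0) return(0)
  h / corr
}

# closed-form raw moments of a lognormal(meanlog, sdlog)
lognormal_moments <- function(meanlog, sdlog) {
  m <- exp((1:4) * meanlog + (1:4)^2 * sdlog^2 / 2)
  mu <- m[1]
  v <- m[2] - mu^2
  m3 <- m[3] - 3 * mu * m[2] + 2 * mu^3
  m4 <- m[4] - 4 * mu * m[3] + 6 * mu^2 * m[2] - 3 * mu^4
  c(mean = mu, sd = sqrt(v), skew = m3 / v^1.5, kurt = m4 / v^2)
}

# batch-resampling Monte-Carlo SE of a moment statistic at sample size n
batch_se <- function(x, stat, n_batches = 20) {
  b <- vapply(split(x, rep(seq_len(n_batches),
                           each = length(x) / n_batches)),
              stat, numeric(1))
  sd(b) / sqrt(n_batches)
}
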
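# Nonparametric group-comparison chain: Lilliefors-style normality
# screen, Kruskal-Wallis across groups, Dunn's rank-based pairwise
# comparisons with Bonferroni correction, and notched-boxplot summaries.

# one-sample KS statistic of x against N(mean(x), sd(x))
ks_stat_normal <- function(x) {
  n <- length(x)
  u <- stats::pnorm(sort(x), mean(x), stats::sd(x))
  max(seq_len(n) / n - u, u - (seq_len(n) - 1) / n)
}

#' Normality screen: Kolmogorov-Smirnov with estimated parameters
#'
#' One-sample KS test against a normal with mean and SD estimated from
#' the data. Because estimation shrinks the statistic, the null
#' distribution is obtained Lilliefors-style by seeded Monte Carlo:
#' `n_null` normal samples of the same size, each re-estimated, give the
#' reference distribution of the statistic.
#'
#' @param values numeric, n >= 5.
#' @param n_null Monte-Carlo null replicates (default 10000).
#' @param seed integer seed for the null simulation.
#' @param null_stats optional precomputed null statistics for this n
#'   (from [ks_null_table()]), reused across many tests of equal size.
#' @return list of class `ks_norm` with `statistic`, `p_value`,
#'   `degenerate`.
#' @export
ks_normality <- function(values, n_null = 10000, seed = 1,
                         null_stats = NULL) {
  n <- length(values)
  if (n < 5) stop_bad_arg("normality screen needs n >= 5")
  if (stats::sd(values) == 0) {
    return(structure(list(statistic = NA_real_,
                          p_value = .Machine$double.xmin,
                          degenerate = TRUE), class = "ks_norm"))
  }
  d <- ks_stat_normal(values)
  if (is.null(null_stats)) null_stats <- ks_null_table(n, n_null, seed)
  p <- (1 + sum(null_stats >= d)) / (length(null_stats) + 1)
  structure(list(statistic = d, p_value = p, degenerate = FALSE),
            class = "ks_norm")
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' @param n sample size.
#' @param n_null replicates.
#' @param seed integer seed.
#' @return numeric vector of null statistics, reusable across tests of
#'   the same sample size.
#' @export
ks_null_table <- function(n, n_null = 10000, seed = 1) {
  set.seed(as.integer(seed))
  vapply(seq_len(n_null),
         function(i) ks_stat_normal(stats::rnorm(n)), numeric(1))
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based omnibus comparison of k groups with midrank tie handling
#' and the standard tie correction; the statistic is referred to a
#' chi-square with k-1 degrees of freedom. When every observation is
#' identical the statistic is 0 and p = 1.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each
#'   nonempty, total N >= 3).
#' @param alpha significance level carried into the result (default 0.05).
#' @return list of class `kw_result`: `statistic`, `df`, `p_value`,
#'   `alpha`, `n`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop_bad_arg("need >= 2 groups")
  if (any(!lengths(groups))) stop_bad_arg("every group must be nonempty")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop_bad_arg("total N must be >= 3")
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
  }
  structure(list(statistic = h, df = length(groups) - 1, p_value = p,
                 alpha = alpha, n = lengths(groups)),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Dunn's pairwise rank comparisons with Bonferroni correction
#'
#' All pairwise z statistics on the pooled midranks,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' the tie term `T = sum(t^3 - t) / (12 (N - 1))`; two-sided normal raw
#' p values are multiplied by the number of pairs and capped at 1.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the `significant` flag.
#' @return tibble: `group1`, `group2`, `z`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
bonferroni_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop_bad_arg("need >= 2 groups")
  nm <- names(groups) %||% as.character(seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(values)
  r <- rank(values)  # midranks
  idx <- rep(seq_len(k), n)
  rbar <- vapply(seq_len(k), function(i) mean(r[idx == i]), numeric(1))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  i <- pairs[1, ]; j <- pairs[2, ]
  se <- sqrt(v0 * (1 / n[i] + 1 / n[j]))
  dz <- rbar[i] - rbar[j]
  z <- ifelse(dz == 0, 0, dz / se)
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(1, m * p_raw)
  tibble::tibble(group1 = nm[i], group2 = nm[j], z = z, p_raw = p_raw,
                 p_adj = p_adj, significant = p_adj < alpha)
}

#' Full nonparametric comparison chain for one endpoint
#'
#' Kruskal-Wallis omnibus test followed by Dunn-Bonferroni pairwise
#' comparisons; pairwise flags are gated on the omnibus test being
#' significant at `alpha` (no pair is flagged when the omnibus test does
#' not reject).
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return list of class `kw_chain`: `kw` ([kruskal_wallis()] result),
#'   `pairwise` tibble with gated `significant` flags, `alpha`.
#' @export
group_chain <- function(groups, alpha = 0.05) {
  kw <- kruskal_wallis(groups, alpha = alpha)
  pw <- bonferroni_posthoc(groups, alpha = alpha)
  if (kw$p_value >= alpha) pw$significant <- FALSE
  structure(list(kw = kw, pairwise = pw, alpha = alpha),
            class = "kw_chain")
}

#' @export
print.kw_chain <- function(x, ...) {
  print(x$kw)
  sig <- x$pairwise[x$pairwise$significant, ]
  if (nrow(sig)) {
    cat("significant pairs:",
        paste(sig$group1, "vs", sig$group2, collapse = ", "), "\n")
  } else cat("no significant pairs\n")
  invisible(x)
}

#' Notched-boxplot summary of one sample
#'
#' Median and quartiles (linear interpolation), notch half-width
#' `1.57 * IQR / sqrt(n)` (the approximate 95% median interval drawn as
#' the box chamfer), and outlier fences at 1.5 IQR.
#'
#' @param values nonempty numeric vector.
#' @return one-row tibble: n, median, q1, q3, iqr, notch_half,
#'   notch_lo, notch_hi, fence_lo, fence_hi, n_outliers.
#' @export
box_summary <- function(values) {
  if (!length(values)) stop_bad_arg("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  notch <- 1.57 * iqr / sqrt(length(values))
  fl <- q[1] - 1.5 * iqr
  fh <- q[3] + 1.5 * iqr
  tibble::tibble(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
                 iqr = iqr, notch_half = notch,
                 notch_lo = q[2] - notch, notch_hi = q[2] + notch,
                 fence_lo = fl, fence_hi = fh,
                 n_outliers = sum(values < fl | values > fh))
}
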
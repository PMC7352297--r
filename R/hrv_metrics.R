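# Time-domain HRV metrics and R-R distribution characterization.
# All intervals are in seconds; HR is in beats per minute.

#' Average heart rate of an R-R series
#'
#' HR = 60 / mean(RR), beats per minute.
#'
#' @param rr an [rr_series()] or numeric vector of intervals, seconds.
#' @return heart rate, bpm.
#' @export
heart_rate <- function(rr) {
  rr <- as.numeric(rr)
  if (!length(rr)) stop_bad_arg("empty R-R series")
  60 / mean(rr)
}

#' SDNN: standard deviation of normal-to-normal intervals
#'
#' Sample standard deviation (N-1 denominator) of the R-R intervals, the
#' overall time-domain HRV index.
#'
#' @param rr an [rr_series()] or numeric vector, length >= 2.
#' @return SDNN, seconds.
#' @export
sdnn <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 2) stop_bad_arg("SDNN needs >= 2 intervals")
  stats::sd(rr)
}

#' RMSSD: root mean square of successive differences
#'
#' sqrt(mean of squared successive R-R differences), with the mean taken
#' over the N-1 differences; the short-term, vagally dominated HRV index.
#'
#' @param rr an [rr_series()] or numeric vector, length >= 2.
#' @return RMSSD, seconds.
#' @export
rmssd <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 2) stop_bad_arg("RMSSD needs >= 2 intervals")
  sqrt(mean(diff(rr)^2))
}

#' Four moments of an R-R distribution
#'
#' Mean, SD (N-1), and the standardized third and fourth moments
#' computed from biased central sample moments: skewness = m3 / m2^(3/2),
#' kurtosis = m4 / m2^2 in the non-excess convention (Gaussian = 3).
#' With `bias_correct = TRUE` the adjusted Fisher-Pearson skewness and
#' the bias-corrected kurtosis are reported instead.
#'
#' @param rr an [rr_series()] or numeric vector, length >= 4.
#' @param bias_correct use bias-corrected shape estimators.
#' @return a [moment_set()]; for zero-variance input the shape moments
#'   are `NA` and the result carries attribute `degenerate = TRUE`.
#' @export
distribution_moments <- function(rr, bias_correct = FALSE) {
  x <- as.numeric(rr)
  n <- length(x)
  if (n < 4) stop_bad_arg("moments need >= 4 intervals")
  m2 <- central_moment(x, 2)
  if (m2 == 0) {
    out <- structure(list(mean = mean(x), sd = 0, skewness = NA_real_,
                          kurtosis = NA_real_), class = "moment_set")
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  g1 <- central_moment(x, 3) / m2^1.5
  b2 <- central_moment(x, 4) / m2^2
  if (bias_correct) {
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
    b2 <- ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3)) + 3
  }
  # estimates are reported as computed (biased sample moments always
  # satisfy the feasibility bound; bias-corrected ones may graze it)
  structure(list(mean = mean(x), sd = stats::sd(x), skewness = g1,
                 kurtosis = b2), class = "moment_set")
}

#' Histogram of R-R intervals
#'
#' Equal-width bins spanning the sample range; counts conserve the
#' series length.
#'
#' @param rr an [rr_series()] or nonempty numeric vector.
#' @param n_bins number of bins (>= 1).
#' @return list of class `rr_histogram` with `breaks`, `counts`, `range`.
#' @export
rr_histogram <- function(rr, n_bins = 20) {
  x <- as.numeric(rr)
  if (!length(x)) stop_bad_arg("empty R-R series")
  if (n_bins < 1) stop_bad_arg("n_bins must be >= 1")
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-1, 1) * 1e-9
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = breaks, include.lowest = TRUE,
                      right = TRUE, plot = FALSE)
  structure(list(breaks = breaks, counts = h$counts, range = rng),
            class = "rr_histogram")
}

#' Per-epoch HRV metrics row
#'
#' @param rr an [rr_series()] with provenance attributes.
#' @return one-row tibble: animal_id, group, epoch, hr_bpm, sdnn_s,
#'   rmssd_s, n_beats.
#' @export
hrv_metrics <- function(rr) {
  tibble::tibble(
    animal_id = attr(rr, "animal_id") %||% NA_character_,
    group = attr(rr, "group") %||% NA_character_,
    epoch = attr(rr, "epoch") %||% NA_integer_,
    hr_bpm = heart_rate(rr),
    sdnn_s = sdnn(rr),
    rmssd_s = rmssd(rr),
    n_beats = length(rr) + 1L)
}

#' Pool per-epoch HRV metrics
#'
#' Stacks per-epoch rows (the statistical unit used for the group
#' comparisons) and additionally aggregates to per-animal means for
#' sensitivity analysis.
#'
#' @param per_epoch list of one-row tibbles from [hrv_metrics()], or a
#'   tibble of such rows.
#' @return list with `per_epoch` (one row per epoch per animal) and
#'   `per_animal` (means over epochs).
#' @export
pool_epochs <- function(per_epoch) {
  if (is.data.frame(per_epoch)) {
    tab <- tibble::as_tibble(per_epoch)
  } else {
    if (!length(per_epoch)) stop_bad_arg("no epochs to pool")
    tab <- do.call(rbind, per_epoch)
  }
  agg <- stats::aggregate(
    tab[c("hr_bpm", "sdnn_s", "rmssd_s", "n_beats")],
    by = list(animal_id = tab$animal_id, group = tab$group),
    FUN = mean)
  list(per_epoch = tab, per_animal = tibble::as_tibble(agg))
}
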
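# R-R interval process simulation: fixtures with known ground truth for
# the detection/metrics stages. Intervals are in seconds throughout.

#' Parameters of a simulated R-R interval process
#'
#' Describes a stationary R-R generating process: either i.i.d. Gaussian
#' intervals, or a stationary AR(1) process whose marginal SD is `sd_rr`
#' and whose successive-difference SD (the scale RMSSD estimates) is
#' `sd_rr * sqrt(2 * (1 - ar1_rho))`. Supply either `ar1_rho` or
#' `short_term_sd`; if `short_term_sd` is given the lag-1 correlation is
#' derived from the contract above.
#'
#' @param mean_rr mean interval, seconds (> 0).
#' @param sd_rr marginal SD of intervals, seconds (>= 0).
#' @param model `"iid_gaussian"` or `"ar1"`.
#' @param ar1_rho lag-1 correlation in (-1, 1) (AR(1) model).
#' @param short_term_sd successive-difference SD, seconds; alternative
#'   way to pin down `ar1_rho`.
#' @return an object of class `rr_process_params`.
#' @export
rr_process_params <- function(mean_rr, sd_rr,
                              model = c("iid_gaussian", "ar1"),
                              ar1_rho = NULL, short_term_sd = NULL) {
  model <- match.arg(model)
  if (mean_rr <= 0 || sd_rr < 0)
    stop_bad_arg("mean_rr must be > 0 and sd_rr >= 0")
  if (mean_rr - 4 * sd_rr <= 0)
    stop_bad_arg(sprintf(
      "infeasible R-R process: mean_rr - 4*sd_rr = %.4f s must be > 0 ",
      mean_rr - 4 * sd_rr),
      "(intervals would routinely be nonpositive)")
  if (model == "ar1") {
    if (is.null(ar1_rho)) {
      if (is.null(short_term_sd))
        stop_bad_arg("ar1 model needs `ar1_rho` or `short_term_sd`")
      if (sd_rr <= 0)
        stop_bad_arg("short_term_sd requires sd_rr > 0")
      ar1_rho <- 1 - (short_term_sd / sd_rr)^2 / 2
    }
    if (ar1_rho <= -1 || ar1_rho >= 1)
      stop_bad_arg("ar1_rho must lie in (-1, 1); got ", ar1_rho)
    short_term_sd <- sd_rr * sqrt(2 * (1 - ar1_rho))
  } else {
    ar1_rho <- 0
    short_term_sd <- sd_rr * sqrt(2)
  }
  structure(list(mean_rr = mean_rr, sd_rr = sd_rr, model = model,
                 ar1_rho = ar1_rho, short_term_sd = short_term_sd),
            class = "rr_process_params")
}

#' Construct an R-R interval series (tachogram)
#'
#' @param intervals numeric vector of intervals, seconds, all > 0.
#' @param animal_id,group,epoch provenance labels.
#' @param n_clipped number of intervals raised to the positivity floor.
#' @return numeric vector of class `rr_series` with provenance attributes.
#' @export
rr_series <- function(intervals, animal_id = NA_character_,
                      group = NA_character_, epoch = NA_integer_,
                      n_clipped = 0L) {
  if (any(intervals <= 0))
    stop_bad_arg("all R-R intervals must be > 0")
  structure(as.numeric(intervals), class = "rr_series",
            animal_id = animal_id, group = group, epoch = epoch,
            n_clipped = as.integer(n_clipped))
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("rr_series: %d intervals, mean %.4f s (animal %s, group %s, epoch %s)\n",
              length(x), mean(x), attr(x, "animal_id"), attr(x, "group"),
              format(attr(x, "epoch"))))
  invisible(x)
}

#' Simulate an R-R interval series from a stationary process
#'
#' Draws `n` intervals from the process in `params`. Intervals falling
#' below the physiological floor of 0.05 s are raised to the floor and
#' counted (`n_clipped` attribute); the feasibility precondition
#' `mean_rr - 4*sd_rr > 0` makes clipping a rare-tail event only.
#'
#' @param params an [rr_process_params()].
#' @param n number of intervals (>= 2).
#' @param seed integer seed.
#' @param animal_id,group,epoch provenance labels passed to [rr_series()].
#' @return an `rr_series` of length `n`.
#' @export
simulate_rr_series <- function(params, n, seed, animal_id = NA_character_,
                               group = NA_character_, epoch = NA_integer_) {
  stopifnot(inherits(params, "rr_process_params"))
  if (n < 2) stop_bad_arg("n must be >= 2")
  set.seed(as.integer(seed))
  if (params$sd_rr == 0) {
    x <- rep(params$mean_rr, n)
  } else if (params$model == "iid_gaussian") {
    x <- stats::rnorm(n, params$mean_rr, params$sd_rr)
  } else {
    rho <- params$ar1_rho
    innov_sd <- params$sd_rr * sqrt(1 - rho^2)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, params$sd_rr)
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) x[i] <- rho * x[i - 1] + e[i - 1]
    x <- params$mean_rr + x
  }
  floor_s <- 0.05
  n_clipped <- sum(x < floor_s)
  x[x < floor_s] <- floor_s
  rr_series(x, animal_id = animal_id, group = group, epoch = epoch,
            n_clipped = n_clipped)
}
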
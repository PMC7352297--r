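# Weekly body-weight trajectories for the four-group cohort design.

#' Cohort design for weight trajectories
#'
#' Defaults emulate a 40-day, four-group design weighed at seven time
#' points: per-group day-0 means/SDs and day-40 targets translate into
#' per-interval gains, with per-animal gain noise chosen so the final
#' dispersion matches the day-40 SDs
#' (`gain_sd = sqrt((end_sd^2 - start_sd^2) / n_intervals)`).
#'
#' @param groups group labels.
#' @param n_per_group animals per group.
#' @param weight_start_mean,weight_start_sd day-0 weight mean/SD, grams.
#' @param weight_end_mean,weight_end_sd final-day weight mean/SD, grams.
#' @param days measurement days.
#' @param seed integer seed.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c("sham", "sham_p", "ohda", "ohda_p"),
                          n_per_group = c(13, 13, 9, 9),
                          weight_start_mean = c(311.3, 310.2, 307.7, 313.7),
                          weight_start_sd = c(4.392, 6.9, 10.2, 11.11),
                          weight_end_mean = c(428.8, 434.2, 374.7, 392.8),
                          weight_end_sd = c(26.6, 27.13, 11.15, 9.704),
                          days = c(0, 7, 14, 21, 28, 34, 40),
                          seed = 1) {
  k <- length(groups)
  stopifnot(length(n_per_group) == k, length(weight_start_mean) == k,
            length(weight_start_sd) == k, length(weight_end_mean) == k,
            length(weight_end_sd) == k)
  if (any(n_per_group < 1)) stop_bad_arg("all group sizes must be >= 1")
  if (any(weight_start_mean <= 0)) stop_bad_arg("weights must be > 0")
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 weight_start_mean = weight_start_mean,
                 weight_start_sd = weight_start_sd,
                 weight_end_mean = weight_end_mean,
                 weight_end_sd = weight_end_sd,
                 days = days, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate weekly weight trajectories
#'
#' Each animal starts at a Gaussian draw around its group's day-0 mean
#' and accrues independent Gaussian per-interval gains whose mean drifts
#' the group toward its final-day target.
#'
#' @param design a [cohort_design()].
#' @return tibble with columns `animal_id`, `group`, `day`, `weight_g`.
#' @export
simulate_weights <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  nint <- length(design$days) - 1L
  rows <- list()
  aid <- 0L
  for (g in seq_along(design$groups)) {
    gain_mu <- (design$weight_end_mean[g] - design$weight_start_mean[g]) / nint
    gain_sd <- sqrt(max(0, (design$weight_end_sd[g]^2 -
                              design$weight_start_sd[g]^2) / nint))
    for (a in seq_len(design$n_per_group[g])) {
      aid <- aid + 1L
      w0 <- stats::rnorm(1, design$weight_start_mean[g],
                         design$weight_start_sd[g])
      gains <- if (nint > 0)
        stats::rnorm(nint, gain_mu, gain_sd) else numeric(0)
      w <- cumsum(c(w0, gains))
      rows[[aid]] <- tibble::tibble(
        animal_id = sprintf("r%03d", aid),
        group = design$groups[g],
        day = design$days,
        weight_g = w)
    }
  }
  do.call(rbind, rows)
}
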
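# Stationary epoch selection.

make_noise_record <- function(minute_sd, fs = 100) {
  # one value of minute_sd per minute of record
  set.seed(99)
  x <- unlist(lapply(minute_sd, function(s) rnorm(60 * fs, 0, s)))
  ecg_record(x, fs)
}

test_that("a fully stationary record yields the consecutive minutes", {
  ecg <- make_noise_record(rep(1, 8))
  spans <- select_epochs(ecg, epoch_plan(n_epochs = 8))
  expect_length(spans, 8)
  starts <- vapply(spans, `[[`, numeric(1), "start")
  expect_equal(starts, seq(1, by = 60 * 100, length.out = 8))
  lens <- vapply(spans, function(s) s$end - s$start + 1, numeric(1))
  expect_true(all(lens == 60 * 100))
})

test_that("a minute with tenfold amplitude variance is excluded", {
  ecg <- make_noise_record(c(1, 1, 1, 1, sqrt(10), 1, 1, 1, 1))
  spans <- select_epochs(ecg, epoch_plan(n_epochs = 8))
  expect_length(spans, 8)
  starts <- vapply(spans, `[[`, numeric(1), "start")
  bad_start <- 4 * 60 * 100 + 1
  expect_false(bad_start %in% starts)
})

test_that("too-short records are rejected with the epoch count", {
  ecg <- make_noise_record(rep(1, 3))
  expect_error(select_epochs(ecg, epoch_plan(n_epochs = 8)), "too short")
})

test_that("too few qualifying spans reports how many were found", {
  ecg <- make_noise_record(c(1, 5, 1, 5, 1, 5, 1, 5))
  expect_error(select_epochs(ecg, epoch_plan(n_epochs = 8)),
               "only [0-9]+ of the requested 8")
})

test_that("epoch slicing re-indexes ground-truth beats", {
  rr <- rep(0.2, 600)  # two minutes of beats
  ecg <- synthesize_ecg(rr, ecg_synth_params(noise_sd = 0.02), seed = 1)
  spans <- select_epochs(ecg, epoch_plan(n_epochs = 2))
  ep2 <- slice_epoch(ecg, spans[[2]])
  expect_true(all(ep2$ground_truth_beats >= 1 &
                    ep2$ground_truth_beats <= length(ep2$samples)))
  pk <- detect_r_peaks(ep2)
  # every interior beat (full QRS inside the slice) is found within 3
  # samples; beats cut by the slice boundary are exempt
  interior <- ep2$ground_truth_beats[
    ep2$ground_truth_beats > 60 &
      ep2$ground_truth_beats < length(ep2$samples) - 60]
  for (b in interior) expect_lte(min(abs(pk$idx - b)), 3)
})
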
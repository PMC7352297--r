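# Amplitude-threshold R-peak detection.

test_that("sub-threshold and degenerate traces give empty peak sets", {
  flat <- ecg_record(rep(0, 10000), 1000)
  expect_warning(pk <- detect_r_peaks(flat), "constant")
  expect_length(pk$idx, 0)
})

test_that("a single impulse is found at its index", {
  x <- rep(0, 5000); x[1234] <- 1
  pk <- detect_r_peaks(ecg_record(x, 1000))
  expect_identical(pk$idx, 1234L)
})

test_that("two equal impulses inside the refractory gap keep the earlier one", {
  x <- rep(0, 2000); x[1000] <- 1; x[1050] <- 1  # 50 ms apart at 1 kHz
  pk <- detect_r_peaks(ecg_record(x, 1000))
  expect_identical(pk$idx, 1000L)
})

test_that("clean synthetic ECG is recovered exactly (generator closure)", {
  rr <- simulate_rr_series(rr_process_params(0.177, 0.0086), 300, seed = 4)
  ecg <- synthesize_ecg(rr, ecg_synth_params(), seed = 4)  # no noise
  pk <- detect_r_peaks(ecg)
  expect_identical(pk$idx, as.integer(ecg$ground_truth_beats))
})

test_that("moderate noise moves detections by at most 3 samples, no extras", {
  rr <- simulate_rr_series(rr_process_params(0.177, 0.0086), 330, seed = 5)
  ecg <- synthesize_ecg(rr, ecg_synth_params(noise_sd = 0.05), seed = 5)
  pk <- detect_r_peaks(ecg)
  expect_length(pk$idx, length(ecg$ground_truth_beats))
  expect_lte(max(abs(pk$idx - ecg$ground_truth_beats)), 3)
})

test_that("detector equals the brute-force refractory oracle on random traces", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(500:4000, 1)
    fs <- sample(c(250, 500, 1000), 1)
    x <- rnorm(n)
    # sprinkle spikes so some candidates compete inside the gap
    spikes <- sample(n, 15)
    x[spikes] <- x[spikes] + runif(15, 2, 6)
    pk <- detect_r_peaks(ecg_record(x, fs))
    expect_identical(pk$idx, brute_detect(x, fs))
  }
})

test_that("refractory spacing holds by construction", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(3000) + 3 * (runif(3000) < 0.02)
    pk <- detect_r_peaks(ecg_record(x, 1000))
    if (length(pk$idx) > 1) expect_gte(min(diff(pk$idx)), 100)
  }
})

test_that("detection is invariant to positive rescaling of the trace", {
  rr <- simulate_rr_series(rr_process_params(0.2, 0.006), 100, seed = 6)
  ecg <- synthesize_ecg(rr, ecg_synth_params(noise_sd = 0.03), seed = 6)
  pk1 <- detect_r_peaks(ecg)
  for (c0 in c(0.2, 5, 1000)) {
    pk2 <- detect_r_peaks(ecg_record(ecg$samples * c0, ecg$fs))
    expect_identical(pk2$idx, pk1$idx)
  }
})

test_that("tachogram arithmetic and preconditions", {
  expect_equal(as.numeric(build_tachogram(peak_set(c(0, 1000, 2000) + 1, 1000))),
               c(1, 1))
  expect_equal(as.numeric(build_tachogram(peak_set(c(0, 150, 362) + 1, 1000))),
               c(0.150, 0.212))
  expect_error(build_tachogram(peak_set(5L, 1000)), "2 peaks")
})

test_that("tachogram matches the generator R-R under light noise", {
  rr <- simulate_rr_series(rr_process_params(0.177, 0.0086), 200, seed = 8)
  ecg <- synthesize_ecg(rr, ecg_synth_params(noise_sd = 0.02), seed = 8)
  tg <- build_tachogram(detect_r_peaks(ecg))
  expect_length(tg, length(rr))
  expect_lt(max(abs(as.numeric(tg) - as.numeric(rr))), 0.003)
})
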
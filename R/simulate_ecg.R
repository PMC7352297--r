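# Synthetic ECG rendering: a QRS-like template stamped at prescribed beat
# times plus baseline wander and white noise. The morphology is a fixture
# for exercising the detector, not a physiological model of rat ECG.

#' Parameters of the synthetic ECG renderer
#'
#' @param fs sampling rate, Hz (default 1000, the acquisition rate the
#'   pipeline is designed around).
#' @param qrs_template `"gaussian_biphasic"` (positive R lobe followed by
#'   a smaller negative S lobe) or `"mexican_hat"` (Ricker wavelet).
#' @param qrs_amplitude R-wave amplitude, mV.
#' @param qrs_width characteristic QRS width, seconds; must stay below
#'   the smallest R-R interval rendered.
#' @param baseline_wander_amplitude amplitude of a slow (0.5 Hz) sinusoidal
#'   baseline drift, mV.
#' @param noise_sd SD of additive white noise, mV.
#' @param duration total record length, seconds; `NULL` = just past the
#'   last beat.
#' @return object of class `ecg_synth_params`.
#' @export
ecg_synth_params <- function(fs = 1000,
                             qrs_template = c("gaussian_biphasic",
                                              "mexican_hat"),
                             qrs_amplitude = 1, qrs_width = 0.012,
                             baseline_wander_amplitude = 0, noise_sd = 0,
                             duration = NULL) {
  qrs_template <- match.arg(qrs_template)
  if (fs <= 0 || qrs_width <= 0 || noise_sd < 0)
    stop_bad_arg("fs and qrs_width must be > 0 and noise_sd >= 0")
  structure(list(fs = fs, qrs_template = qrs_template,
                 qrs_amplitude = qrs_amplitude, qrs_width = qrs_width,
                 baseline_wander_amplitude = baseline_wander_amplitude,
                 noise_sd = noise_sd, duration = duration),
            class = "ecg_synth_params")
}

#' Construct a uniformly sampled ECG record
#'
#' @param samples voltages, mV.
#' @param fs sampling rate, Hz.
#' @param ground_truth_beats optional strictly increasing sample indices
#'   of R peaks (populated by the synthetic generator).
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, ground_truth_beats = NULL) {
  if (!is.null(ground_truth_beats) &&
      any(diff(ground_truth_beats) <= 0))
    stop_bad_arg("ground_truth_beats must be strictly increasing")
  structure(list(samples = as.numeric(samples), fs = fs,
                 ground_truth_beats = ground_truth_beats),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record: %d samples at %g Hz (%.1f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (!is.null(x$ground_truth_beats))
                sprintf(", %d ground-truth beats",
                        length(x$ground_truth_beats)) else ""))
  invisible(x)
}

# render the QRS template on the sample grid; returns the waveform and
# the offset (samples) of its maximum relative to the nominal centre
qrs_waveform <- function(params) {
  fs <- params$fs
  sigma <- params$qrs_width / 2
  half <- ceiling(4 * sigma * fs) + ceiling(3 * sigma * fs)
  t <- (-half:half) / fs
  w <- switch(params$qrs_template,
    gaussian_biphasic =
      exp(-t^2 / (2 * sigma^2)) -
        0.35 * exp(-(t - 2.2 * sigma)^2 / (2 * sigma^2)),
    mexican_hat =
      (1 - (t / sigma)^2) * exp(-t^2 / (2 * sigma^2)))
  w <- w / max(w) * params$qrs_amplitude
  list(w = w, half = half, peak_offset = which.max(w) - (half + 1L))
}

#' Synthesize an ECG record from an R-R interval series
#'
#' Beat times are the cumulative sums of the intervals starting at zero
#' (so an empty series yields a record with the single initial beat). A
#' QRS template is stamped at each beat; slow sinusoidal baseline wander
#' and white noise are added at the configured amplitudes, and samples
#' are quantized to 1 microvolt, the precision at which records are
#' written to disk. `ground_truth_beats` holds the sample index of each
#' rendered R-wave maximum.
#'
#' @param rr R-R intervals, seconds (an [rr_series()] or plain numeric).
#' @param params an [ecg_synth_params()].
#' @param seed integer seed for the noise.
#' @return an [ecg_record()] with ground-truth beat indices.
#' @export
synthesize_ecg <- function(rr, params = ecg_synth_params(), seed = 1) {
  stopifnot(inherits(params, "ecg_synth_params"))
  rr <- as.numeric(rr)
  if (length(rr) && params$qrs_width >= min(rr))
    stop_bad_arg("qrs_width >= min(rr): QRS complexes would overlap")
  fs <- params$fs
  beat_t <- cumsum(c(0, rr))
  qrs <- qrs_waveform(params)
  duration <- params$duration %||%
    (beat_t[length(beat_t)] + (qrs$half + 1) / fs)
  n <- ceiling(duration * fs)
  if (beat_t[length(beat_t)] * fs > n - 1)
    stop_bad_arg("cumulative R-R intervals exceed the requested duration")
  x <- numeric(n)
  centres <- as.integer(round(beat_t * fs)) + 1L
  for (c0 in centres) {
    lo <- max(1L, c0 - qrs$half)
    hi <- min(n, c0 + qrs$half)
    x[lo:hi] <- x[lo:hi] + qrs$w[(lo - c0 + qrs$half + 1L):(hi - c0 + qrs$half + 1L)]
  }
  set.seed(as.integer(seed))
  if (params$baseline_wander_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + params$baseline_wander_amplitude *
      sin(2 * pi * 0.5 * (seq_len(n) - 1) / fs + phase)
  }
  if (params$noise_sd > 0)
    x <- x + stats::rnorm(n, 0, params$noise_sd)
  x <- round(x, 3)  # 1 uV quantization on the mV scale
  truth <- centres + as.integer(qrs$peak_offset)
  truth <- truth[truth >= 1 & truth <= n]
  ecg_record(x, fs, ground_truth_beats = truth)
}
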
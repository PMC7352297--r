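# R-peak detection and epoch selection. The detection rule: a peak is a
# local maximum whose amplitude exceeds the signal mean plus 70% of its
# standard deviation, with a minimum distance of 100 ms between peaks.

#' R-peak detector parameters
#'
#' @param threshold_factor multiple of the signal SD added to the mean to
#'   form the amplitude threshold (default 0.7).
#' @param min_distance refractory spacing between accepted peaks, seconds
#'   (default 0.100).
#' @param threshold_scope `"per_epoch"` (threshold statistics computed on
#'   each analyzed stretch, the default) or `"whole_record"`.
#' @return object of class `detector_params`.
#' @export
detector_params <- function(threshold_factor = 0.7, min_distance = 0.100,
                            threshold_scope = c("per_epoch",
                                                "whole_record")) {
  threshold_scope <- match.arg(threshold_scope)
  if (threshold_factor <= 0 || min_distance <= 0)
    stop_bad_arg("threshold_factor and min_distance must be > 0")
  structure(list(threshold_factor = threshold_factor,
                 min_distance = min_distance,
                 threshold_scope = threshold_scope),
            class = "detector_params")
}

#' Epoch selection plan
#'
#' @param n_epochs number of stretches to select (default 8).
#' @param epoch_length stretch length, seconds (default 60).
#' @param stationarity_window rolling window for the stationarity screen,
#'   seconds (default 5).
#' @param stationarity_max_cv maximum coefficient of variation of the
#'   rolling-window amplitude SD within a qualifying stretch (default 0.5).
#' @param stationarity_max_level_ratio maximum allowed ratio between a
#'   stretch's median window SD and the record-wide median window SD
#'   (default 2); stretches whose amplitude regime departs from the
#'   record's dominant regime by more than this factor are rejected.
#' @return object of class `epoch_plan`.
#' @export
epoch_plan <- function(n_epochs = 8, epoch_length = 60,
                       stationarity_window = 5, stationarity_max_cv = 0.5,
                       stationarity_max_level_ratio = 2) {
  if (n_epochs < 1 || epoch_length <= 0)
    stop_bad_arg("n_epochs must be >= 1 and epoch_length > 0")
  structure(list(n_epochs = as.integer(n_epochs),
                 epoch_length = epoch_length,
                 stationarity_window = stationarity_window,
                 stationarity_max_cv = stationarity_max_cv,
                 stationarity_max_level_ratio = stationarity_max_level_ratio),
            class = "epoch_plan")
}

#' Construct a set of detected R peaks
#'
#' @param idx strictly increasing sample indices.
#' @param fs sampling rate, Hz.
#' @param amplitude peak amplitudes, mV.
#' @return object of class `peak_set`.
#' @export
peak_set <- function(idx, fs, amplitude = NULL) {
  if (length(idx) > 1 && any(diff(idx) <= 0))
    stop_bad_arg("peak indices must be strictly increasing")
  structure(list(idx = as.integer(idx), fs = fs, amplitude = amplitude),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks at %g Hz\n", length(x$idx), x$fs))
  invisible(x)
}

#' Detect R peaks by amplitude thresholding
#'
#' Candidate peaks are local maxima (strict over a +/- 10 ms
#' neighbourhood; plateaus resolve to their first sample) whose amplitude
#' exceeds `mean(signal) + threshold_factor * sd(signal)`. Candidates are
#' then thinned greedily by descending amplitude (ties: earlier index
#' wins) subject to the `min_distance` refractory spacing, so the
#' returned set satisfies the minimum gap by construction.
#'
#' Because the threshold is an affine function of the signal's own mean
#' and SD, detection is invariant to rescaling the trace by any positive
#' constant.
#'
#' @param ecg an [ecg_record()].
#' @param params a [detector_params()].
#' @return a [peak_set()]. A constant trace (zero SD) yields an empty
#'   set with a warning.
#' @export
detect_r_peaks <- function(ecg, params = detector_params()) {
  stopifnot(inherits(ecg, "ecg_record"))
  x <- ecg$samples
  fs <- ecg$fs
  if (length(x) < 2) stop_bad_arg("record must have >= 2 samples")
  sdv <- stats::sd(x)
  if (sdv == 0) {
    warning("constant signal: no peaks detectable", call. = FALSE)
    return(peak_set(integer(0), fs, numeric(0)))
  }
  thr <- mean(x) + params$threshold_factor * sdv
  win <- max(1L, round(0.010 * fs))  # +/- 10 ms neighbourhood
  rmax <- running_max(x, win)
  cand <- which(x > thr & x >= rmax)
  if (length(cand) > 1) {
    # plateau resolution: drop candidates continuing a run of equal,
    # consecutive samples; keep the first sample of each plateau
    same_plateau <- diff(cand) == 1L &
      x[cand[-1]] == x[cand[-length(cand)]]
    run_start <- c(TRUE, !same_plateau)
    cand <- cand[run_start]
  }
  min_gap <- round(params$min_distance * fs)
  ord <- order(-x[cand], cand)
  kept <- integer(0)
  for (j in ord) {
    i <- cand[j]
    if (!length(kept) || all(abs(kept - i) >= min_gap))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  peak_set(kept, fs, amplitude = x[kept])
}

#' Select stationary analysis epochs from a record
#'
#' Partitions the record into consecutive candidate stretches of
#' `epoch_length` and screens each for stationarity: the coefficient of
#' variation of the rolling-window amplitude SD inside the stretch must
#' not exceed `stationarity_max_cv`, and the stretch's median window SD
#' must stay within `stationarity_max_level_ratio` of the record-wide
#' median (so a stretch whose amplitude regime differs wholesale from
#' the rest of the recording is rejected even if internally uniform).
#' The first `n_epochs` qualifying stretches are returned in temporal
#' order.
#'
#' @param ecg an [ecg_record()].
#' @param plan an [epoch_plan()].
#' @return list of epoch spans, each a list with `start`, `end` (sample
#'   indices) and `epoch` id.
#' @export
select_epochs <- function(ecg, plan = epoch_plan()) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$fs
  n <- length(ecg$samples)
  len <- round(plan$epoch_length * fs)
  if (n < plan$n_epochs * len)
    stop_bad_arg(sprintf(
      "record too short: %d epochs of %g s need %d samples, have %d",
      plan$n_epochs, plan$epoch_length, plan$n_epochs * len, n))
  wlen <- max(2L, round(plan$stationarity_window * fs))
  nwin <- n %/% wlen
  wsd <- vapply(seq_len(nwin), function(k) {
    stats::sd(ecg$samples[((k - 1) * wlen + 1):(k * wlen)])
  }, numeric(1))
  med_all <- stats::median(wsd)
  starts <- seq(1L, n - len + 1L, by = len)
  spans <- list()
  for (s in starts) {
    if (length(spans) >= plan$n_epochs) break
    kidx <- which((seq_len(nwin) - 1) * wlen + 1 >= s &
                    seq_len(nwin) * wlen <= s + len - 1)
    if (length(kidx) < 2) next
    v <- wsd[kidx]
    cv <- stats::sd(v) / mean(v)
    lev <- stats::median(v) / med_all
    if (cv <= plan$stationarity_max_cv &&
        lev <= plan$stationarity_max_level_ratio &&
        lev >= 1 / plan$stationarity_max_level_ratio) {
      spans[[length(spans) + 1L]] <-
        list(start = s, end = s + len - 1L,
             epoch = length(spans) + 1L)
    }
  }
  if (length(spans) < plan$n_epochs)
    stop_bad_arg(sprintf(
      "only %d of the requested %d stationary epochs found",
      length(spans), plan$n_epochs))
  spans
}

#' Slice an ECG record to an epoch span
#'
#' @param ecg an [ecg_record()].
#' @param span one element of the list returned by [select_epochs()].
#' @return an [ecg_record()] covering the span; ground-truth beats are
#'   re-indexed relative to the span start.
#' @export
slice_epoch <- function(ecg, span) {
  gt <- ecg$ground_truth_beats
  if (!is.null(gt)) {
    gt <- gt[gt >= span$start & gt <= span$end] - span$start + 1L
    if (!length(gt)) gt <- NULL
  }
  ecg_record(ecg$samples[span$start:span$end], ecg$fs,
             ground_truth_beats = gt)
}

#' Build the tachogram from a set of R peaks
#'
#' @param peaks a [peak_set()] with at least two peaks.
#' @param animal_id,group,epoch provenance labels.
#' @return an [rr_series()] with `intervals[i] = (idx[i+1] - idx[i]) / fs`.
#' @export
build_tachogram <- function(peaks, animal_id = NA_character_,
                            group = NA_character_, epoch = NA_integer_) {
  stopifnot(inherits(peaks, "peak_set"))
  if (length(peaks$idx) < 2)
    stop_bad_arg("need at least 2 peaks to build a tachogram")
  rr_series(diff(peaks$idx) / peaks$fs, animal_id = animal_id,
            group = group, epoch = epoch)
}
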
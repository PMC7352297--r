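# Plain-text readers and writers for every pipeline artifact. ECG CSVs
# hold time in seconds on the exact sampling grid and voltage in mV at
# 1 uV precision, so a write/read round trip is lossless.

#' Write an ECG record as CSV (`t_s,mV`)
#'
#' @param ecg an [ecg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  n <- length(ecg$samples)
  df <- data.frame(t_s = sprintf("%.6f", (seq_len(n) - 1) / ecg$fs),
                   mV = sprintf("%.3f", ecg$samples))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV (`t_s,mV`)
#'
#' The time column must be strictly increasing and uniformly spaced;
#' violations are rejected with the offending line reported.
#'
#' @param path CSV path.
#' @return an [ecg_record()] (sampling rate inferred from the grid).
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "mV") %in% names(df)))
    stop_bad_arg("ECG CSV must have columns t_s and mV: ", path)
  dt <- diff(df$t_s)
  bad <- which(dt <= 0)
  if (length(bad))
    stop_bad_arg(sprintf(
      "non-monotone time column at line %d of %s", bad[1] + 2L, path))
  if (max(dt) - min(dt) > 1e-9 + 1e-6 * stats::median(dt))
    stop_bad_arg("time column is not uniformly sampled: ", path)
  ecg_record(df$mV, fs = 1 / stats::median(dt))
}

#' Write detected peaks as CSV (`sample_index,t_s,amplitude_mV`)
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- data.frame(sample_index = peaks$idx,
                   t_s = sprintf("%.6f", (peaks$idx - 1) / peaks$fs),
                   amplitude_mV = sprintf("%.3f",
                                          peaks$amplitude %||%
                                            rep(NA_real_,
                                                length(peaks$idx))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write R-R interval series as CSV (`animal_id,group,epoch,rr_s`)
#'
#' @param rr_list list of [rr_series()] objects (or a single series).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr_list, path) {
  if (inherits(rr_list, "rr_series")) rr_list <- list(rr_list)
  rows <- lapply(rr_list, function(rr) {
    data.frame(animal_id = attr(rr, "animal_id"),
               group = attr(rr, "group"),
               epoch = attr(rr, "epoch"),
               rr_s = sprintf("%.6f", as.numeric(rr)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read R-R interval series from CSV
#'
#' @param path CSV with columns `animal_id,group,epoch,rr_s`.
#' @return list of [rr_series()] split by animal and epoch.
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("animal_id", "group", "epoch", "rr_s")
  if (!all(need %in% names(df)))
    stop_bad_arg("R-R CSV must have columns ", paste(need, collapse = ","))
  key <- interaction(df$animal_id, df$epoch, drop = TRUE)
  lapply(split(df, key), function(d) {
    rr_series(d$rr_s, animal_id = d$animal_id[1], group = d$group[1],
              epoch = d$epoch[1])
  })
}

#' Serialize a pipeline configuration to YAML
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path.
#' @return a validated [pipeline_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_bad_arg("invalid config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Hash a configuration for output manifests
#'
#' @param config a [pipeline_config()].
#' @return 8-hex-digit hash of the YAML serialization.
#' @export
config_hash <- function(config) {
  fnv1a_hash(yaml::as.yaml(unclass(config)))
}
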
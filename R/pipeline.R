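# End-to-end orchestration: simulate a four-group cohort, run every
# analysis stage, and write a report bundle (CSV tables, stats JSON,
# notched boxplots and R-R histograms, manifest). Identical seeds give
# byte-identical tables.

#' Pipeline configuration
#'
#' Central, serializable description of a full synthetic-cohort run.
#' The group-level HRV scenario (median HR/SDNN/RMSSD per group), the
#' histology scenario (nuclei deficits and fiber densities relative to
#' control) and the weight design default to the study conditions the
#' package emulates; the remaining knobs size the simulation.
#'
#' @param seed global seed; per-stage seeds are derived by fixed offsets.
#' @param groups group labels.
#' @param hrv_n_per_group animals per group in the ECG arm.
#' @param hr_bpm,sdnn_s,rmssd_s per-group scenario levels.
#' @param n_epochs,epoch_length_s epoch plan for the HRV tables.
#' @param animal_cv between-animal coefficient of variation applied to
#'   the group HRV levels (biological heterogeneity).
#' @param histo_n_per_group animals per group in the histology arm.
#' @param n_sections sections quantified per animal.
#' @param image_size_px micrograph side length, pixels.
#' @param nuclei_base control-level nuclei per section.
#' @param nuclei_deficit per-group fractional nuclei loss vs control.
#' @param fiber_density per-group striatal fiber density (control = 1).
#' @param alpha significance level for the statistical chain.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42,
                            groups = c("sham", "sham_p", "ohda", "ohda_p"),
                            hrv_n_per_group = c(6, 5, 5, 5),
                            hr_bpm = c(339.1, 359.2, 306.7, 323.2),
                            sdnn_s = c(0.008632, 0.01025, 0.005022,
                                       0.007386),
                            rmssd_s = c(0.006963, 0.007532, 0.003804,
                                        0.00499),
                            n_epochs = 8, epoch_length_s = 60,
                            animal_cv = 0.04,
                            histo_n_per_group = c(3, 4, 5, 5),
                            n_sections = 2, image_size_px = 384,
                            nuclei_base = 250,
                            nuclei_deficit = c(0, 0.032, 0.5338, 0.2812),
                            fiber_density = c(1, 1, 0.75, 0.823),
                            alpha = 0.05) {
  k <- length(groups)
  same_len <- c(length(hrv_n_per_group), length(hr_bpm), length(sdnn_s),
                length(rmssd_s), length(histo_n_per_group),
                length(nuclei_deficit), length(fiber_density))
  if (any(same_len != k))
    stop_bad_arg("all per-group fields must have length ", k)
  cfg <- list(seed = as.integer(seed), groups = groups,
              hrv_n_per_group = as.integer(hrv_n_per_group),
              hr_bpm = hr_bpm, sdnn_s = sdnn_s, rmssd_s = rmssd_s,
              n_epochs = as.integer(n_epochs),
              epoch_length_s = epoch_length_s, animal_cv = animal_cv,
              histo_n_per_group = as.integer(histo_n_per_group),
              n_sections = as.integer(n_sections),
              image_size_px = as.integer(image_size_px),
              nuclei_base = as.integer(nuclei_base),
              nuclei_deficit = nuclei_deficit,
              fiber_density = fiber_density, alpha = alpha)
  structure(cfg, class = "pipeline_config")
}

# per-animal HRV scenario draws (group level +/- biological jitter)
animal_hrv_levels <- function(config) {
  set.seed(stage_seed(config$seed, "rr", 9L))
  rows <- list()
  aid <- 0L
  for (g in seq_along(config$groups)) {
    for (a in seq_len(config$hrv_n_per_group[g])) {
      aid <- aid + 1L
      jit <- stats::rnorm(3, 1, config$animal_cv)
      rows[[aid]] <- tibble::tibble(
        animal_id = sprintf("r%03d", aid),
        group = config$groups[g],
        mean_rr = 60 / config$hr_bpm[g] * jit[1],
        sdnn = config$sdnn_s[g] * abs(jit[2]),
        rmssd = config$rmssd_s[g] * abs(jit[3]))
    }
  }
  do.call(rbind, rows)
}

#' Simulate the per-epoch tachograms of the whole ECG arm
#'
#' Each animal receives group-level HR/SDNN/RMSSD targets with
#' between-animal jitter; each epoch is an AR(1) R-R series whose
#' marginal SD matches the animal's SDNN level and whose lag-1
#' correlation is chosen so the successive-difference SD matches the
#' RMSSD level.
#'
#' @param config a [pipeline_config()].
#' @return list of [rr_series()], one per animal x epoch.
#' @export
simulate_cohort_rr <- function(config) {
  levels <- animal_hrv_levels(config)
  n_sec <- config$epoch_length_s
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(levels))) {
    rho <- 1 - (levels$rmssd[i] / levels$sdnn[i])^2 / 2
    rho <- min(max(rho, -0.99), 0.99)
    pp <- rr_process_params(levels$mean_rr[i], levels$sdnn[i],
                            model = "ar1", ar1_rho = rho)
    n_beats <- max(2L, round(n_sec / levels$mean_rr[i]))
    for (e in seq_len(config$n_epochs)) {
      k <- k + 1L
      out[[k]] <- simulate_rr_series(
        pp, n_beats, seed = stage_seed(config$seed, "rr", i * 100L + e),
        animal_id = levels$animal_id[i], group = levels$group[i],
        epoch = e)
    }
  }
  out
}

# histology arm: synthesize + quantify, one row per animal x section
run_histology_arm <- function(config) {
  rows <- list()
  k <- 0L
  aid <- 0L
  set.seed(stage_seed(config$seed, "histo", 7L))
  jitter_n <- stats::rnorm(sum(config$histo_n_per_group), 1, 0.05)
  jitter_d <- stats::rnorm(sum(config$histo_n_per_group), 1, 0.02)
  for (g in seq_along(config$groups)) {
    for (a in seq_len(config$histo_n_per_group[g])) {
      aid <- aid + 1L
      n_true <- max(0L, round(config$nuclei_base *
                                (1 - config$nuclei_deficit[g]) *
                                abs(jitter_n[aid])))
      dens <- min(1, max(0, config$fiber_density[g] * abs(jitter_d[aid])))
      for (s in seq_len(config$n_sections)) {
        k <- k + 1L
        sd_snc <- stage_seed(config$seed, "histo", aid * 100L + s)
        img_snc <- synthesize_histo_image(histo_image_params(
          region = "snc", n_nuclei = n_true,
          image_size = config$image_size_px, seed = sd_snc))
        img_str <- synthesize_histo_image(histo_image_params(
          region = "striatum", fiber_density = dens,
          image_size = config$image_size_px, seed = sd_snc + 1L))
        rows[[k]] <- tibble::tibble(
          animal_id = sprintf("h%03d", aid),
          group = config$groups[g],
          section = s,
          nuclei_true = n_true,
          nuclei_count = as.integer(count_th_nuclei(img_snc)),
          od = as.numeric(striatal_optical_density(img_str)))
      }
    }
  }
  do.call(rbind, rows)
}

group_split_named <- function(values, groups, order) {
  out <- split(values, factor(groups, levels = order))
  out[lengths(out) > 0]
}

chain_to_json <- function(chain) {
  list(statistic = chain$kw$statistic, df = chain$kw$df,
       p_value = chain$kw$p_value, alpha = chain$alpha,
       pairwise = lapply(seq_len(nrow(chain$pairwise)), function(i) {
         as.list(chain$pairwise[i, ])
       }))
}

#' Run the full synthetic-cohort analysis and write a report bundle
#'
#' Simulates the ECG, histology and weight arms from one seed, computes
#' per-epoch HRV metrics, the per-group moment table, histology
#' quantification with percent reductions versus control, and the
#' Kruskal-Wallis / Dunn-Bonferroni chain for every endpoint; writes
#' CSV tables, JSON statistics, notched boxplots and R-R histograms
#' plus a manifest into `out_dir`. Rerunning with the same config
#' reproduces identical CSV and JSON bytes.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing and returns the tables only.
#' @return invisible list: `hrv` (per-epoch tibble), `moments`
#'   (Table-1-style tibble), `histology`, `reductions`, `weights`,
#'   `stats` (named list of `kw_chain`), `files`.
#' @export
run_full_analysis <- function(config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  grp <- config$groups
  # --- ECG / HRV arm
  rr_all <- simulate_cohort_rr(config)
  hrv_tab <- do.call(rbind, lapply(rr_all, hrv_metrics))
  pooled <- pool_epochs(hrv_tab)
  moments <- do.call(rbind, lapply(grp, function(g) {
    x <- unlist(lapply(rr_all[vapply(rr_all, attr, "", "group") == g],
                       as.numeric))
    m <- distribution_moments(x)
    tibble::tibble(group = g, mean_s = m$mean, sd_s = m$sd,
                   skewness = m$skewness, kurtosis = m$kurtosis)
  }))
  # --- histology arm
  histo <- run_histology_arm(config)
  ctrl <- histo[histo$group == grp[1], ]
  reductions <- do.call(rbind, lapply(grp[-1], function(g) {
    d <- histo[histo$group == g, ]
    tibble::tibble(
      group = g,
      nuclei_reduction_pct =
        as.numeric(percent_reduction(d$nuclei_count, ctrl$nuclei_count)),
      od_reduction_pct =
        as.numeric(percent_reduction(d$od, ctrl$od)))
  }))
  # --- weight arm
  weights <- simulate_weights(cohort_design(
    groups = grp, seed = stage_seed(config$seed, "weights")))
  # --- statistics
  endpoints <- list(
    hr = group_split_named(hrv_tab$hr_bpm, hrv_tab$group, grp),
    sdnn = group_split_named(hrv_tab$sdnn_s, hrv_tab$group, grp),
    rmssd = group_split_named(hrv_tab$rmssd_s, hrv_tab$group, grp),
    od = group_split_named(histo$od, histo$group, grp),
    nuclei = group_split_named(histo$nuclei_count, histo$group, grp))
  d0 <- weights[weights$day == min(weights$day), ]
  dN <- weights[weights$day == max(weights$day), ]
  endpoints$weight_day0 <- group_split_named(d0$weight_g, d0$group, grp)
  endpoints$weight_final <- group_split_named(dN$weight_g, dN$group, grp)
  stats_out <- lapply(endpoints, group_chain, alpha = config$alpha)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(as.data.frame(tab), p, row.names = FALSE,
                       quote = FALSE)
      p
    }
    files <- c(files,
               wr(hrv_tab, "hrv_per_epoch.csv"),
               wr(pooled$per_animal, "hrv_per_animal.csv"),
               wr(moments, "rr_moments.csv"),
               wr(histo, "histology.csv"),
               wr(reductions, "histology_reductions.csv"),
               wr(weights, "weights.csv"))
    sp <- file.path(out_dir, "stats.json")
    jsonlite::write_json(lapply(stats_out, chain_to_json), sp,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, sp)
    # figures: notched boxplots per endpoint, R-R histograms per group
    fp <- file.path(out_dir, "boxplots.png")
    grDevices::png(fp, width = 1200, height = 800)
    graphics::par(mfrow = c(2, 3))
    for (nm in c("hr", "sdnn", "rmssd", "od", "nuclei", "weight_final")) {
      suppressWarnings(
        graphics::boxplot(endpoints[[nm]], notch = TRUE, col = "grey85",
                          main = nm, las = 2))
    }
    grDevices::dev.off()
    hp <- file.path(out_dir, "rr_histograms.png")
    grDevices::png(hp, width = 1200, height = 300)
    graphics::par(mfrow = c(1, length(grp)))
    for (g in grp) {
      x <- unlist(lapply(rr_all[vapply(rr_all, attr, "", "group") == g],
                         as.numeric))
      graphics::hist(x, breaks = 40, main = g, xlab = "R-R (s)",
                     col = "grey85")
    }
    grDevices::dev.off()
    files <- c(files, fp, hp)
    manifest <- list(seed = config$seed,
                     config_hash = config_hash(config),
                     files = basename(files))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
    cfgp <- file.path(out_dir, "config.yaml")
    write_config(config, cfgp)
    files <- c(files, mp, cfgp)
  }
  invisible(list(hrv = hrv_tab, per_animal = pooled$per_animal,
                 moments = moments, histology = histo,
                 reductions = reductions, weights = weights,
                 stats = stats_out, files = files))
}
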
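#!/usr/bin/env Rscript
# Stage 1: simulate the raw inputs of the study -- a demonstration ECG
# recording with known beat times, per-group R-R samples drawn from the
# moment-matched distributions, synthetic micrographs with known ground
# truth, and the weekly weight table. Everything downstream reads these
# files, so the whole analysis is reproducible from one seed.

library(hrvpipe)

seed <- 20260921L
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

# -- demonstration ECG: 9 minutes at 1 kHz, sham-like rhythm ------------
rr <- simulate_rr_series(
  rr_process_params(0.177, 0.0086, model = "ar1", ar1_rho = 0.65),
  n = round(9 * 60 / 0.177), seed = stage_seed(seed, "rr"),
  animal_id = "demo", group = "sham", epoch = NA_integer_)
ecg <- synthesize_ecg(rr, ecg_synth_params(noise_sd = 0.04,
                                           baseline_wander_amplitude = 0.05),
                      seed = stage_seed(seed, "ecg"))
write_ecg_csv(ecg, "results/simulated/demo_ecg.csv")
message(sprintf("demo ECG: %.1f min, %d beats rendered",
                length(ecg$samples) / ecg$fs / 60,
                length(ecg$ground_truth_beats)))

# -- moment-matched R-R samples per group -------------------------------
moment_rows <- list(
  sham   = c(0.1467, 0.0072,  1.5494,  3.4277),
  sham_p = c(0.1723, 0.0143, -0.9413,  4.9860),
  ohda   = c(0.2415, 0.1675,  1.0905,  3.3249),
  ohda_p = c(0.1889, 0.0080, -0.9608, 15.3378))
rr_list <- list()
for (g in names(moment_rows)) {
  r <- moment_rows[[g]]
  spec <- fit_moment_matched(moment_set(r[1], r[2], r[3], r[4]))
  x <- sample_dist(spec, 5000, seed = stage_seed(seed, "rr", match(g, names(moment_rows))),
                   clip_floor = 0.05)
  message(sprintf("%s: Johnson %s fit, %d draws, %d clipped at 0.05 s",
                  g, toupper(spec$family), length(x), attr(x, "n_clipped")))
  rr_list[[g]] <- rr_series(x, animal_id = paste0("pool_", g), group = g,
                            epoch = 1L)
}
write_rr_csv(rr_list, "results/simulated/rr_pooled.csv")

# -- micrographs: SNc nuclei and striatal fiber fields ------------------
dir.create("results/simulated/images", showWarnings = FALSE)
scenarios <- data.frame(
  group = c("sham", "sham_p", "ohda", "ohda_p"),
  n_nuclei = round(250 * (1 - c(0, 0.032, 0.5338, 0.2812))),
  fiber_density = c(1, 1, 0.75, 0.823))
for (i in seq_len(nrow(scenarios))) {
  g <- scenarios$group[i]
  snc <- synthesize_histo_image(histo_image_params(
    region = "snc", n_nuclei = scenarios$n_nuclei[i], image_size = 512,
    seed = stage_seed(seed, "histo", i)))
  write_histo_image(snc, sprintf("results/simulated/images/snc_%s.png", g))
  str <- synthesize_histo_image(histo_image_params(
    region = "striatum", fiber_density = scenarios$fiber_density[i],
    image_size = 512, seed = stage_seed(seed, "histo", 10L + i)))
  write_histo_image(str, sprintf("results/simulated/images/striatum_%s.png", g))
}
message(sprintf("micrographs: %d SNc + %d striatum images written",
                nrow(scenarios), nrow(scenarios)))

# -- weekly weights -----------------------------------------------------
w <- simulate_weights(cohort_design(seed = stage_seed(seed, "weights")))
utils::write.csv(w, "results/simulated/weights.csv", row.names = FALSE,
                 quote = FALSE)
message(sprintf("weights: %d animals x %d days",
                length(unique(w$animal_id)), length(unique(w$day))))
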
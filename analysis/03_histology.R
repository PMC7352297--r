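#!/usr/bin/env Rscript
# Stage 3: quantify the synthetic micrographs -- nuclei counts in the
# SNc images (Otsu threshold, 8-connected components, area filter) and
# striatal optical density (log10 background/pixel ratio) -- and the
# percent reduction of each group versus the control group.

library(hrvpipe)

groups <- c("sham", "sham_p", "ohda", "ohda_p")
res <- do.call(rbind, lapply(groups, function(g) {
  snc <- read_histo_image(sprintf("results/simulated/images/snc_%s.png", g))
  str <- read_histo_image(sprintf("results/simulated/images/striatum_%s.png", g))
  cnt <- count_th_nuclei(snc)
  od <- striatal_optical_density(str)
  truth <- attr(snc, "ground_truth")$n_nuclei
  message(sprintf("%s: %d nuclei counted (truth %d), OD %.4f",
                  g, as.integer(cnt), truth, as.numeric(od)))
  data.frame(group = g, nuclei_count = as.integer(cnt),
             nuclei_truth = truth, od = as.numeric(od))
}))
utils::write.csv(res, "results/histology.csv", row.names = FALSE,
                 quote = FALSE)

ctrl <- res[res$group == "sham", ]
red <- do.call(rbind, lapply(groups[-1], function(g) {
  d <- res[res$group == g, ]
  data.frame(
    group = g,
    nuclei_reduction_pct =
      as.numeric(percent_reduction(d$nuclei_count, ctrl$nuclei_count)),
    od_reduction_pct = as.numeric(percent_reduction(d$od, ctrl$od)))
}))
utils::write.csv(red, "results/histology_reductions.csv",
                 row.names = FALSE, quote = FALSE)
message("percent reductions vs control:")
for (i in seq_len(nrow(red)))
  message(sprintf("  %s: nuclei %.1f%%, striatal OD %.1f%%",
                  red$group[i], red$nuclei_reduction_pct[i],
                  red$od_reduction_pct[i]))
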
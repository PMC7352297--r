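#!/usr/bin/env Rscript
# Stage 4: nonparametric group statistics on every endpoint. Each
# endpoint is screened for normality (Monte-Carlo Lilliefors), compared
# across the four groups with Kruskal-Wallis, and followed up with
# Dunn's pairwise rank tests under Bonferroni correction; notched
# boxplot summaries accompany each endpoint.

library(hrvpipe)

seed <- 20260921L
cfg <- pipeline_config(seed = seed)
res <- run_full_analysis(cfg, out_dir = NULL)

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

endpoints <- list(
  sdnn = split(res$hrv$sdnn_s, res$hrv$group),
  rmssd = split(res$hrv$rmssd_s, res$hrv$group),
  hr = split(res$hrv$hr_bpm, res$hrv$group))
wd <- res$weights[res$weights$day == 40, ]
endpoints$weight_day40 <- split(wd$weight_g, wd$group)
endpoints$nuclei <- split(res$histology$nuclei_count, res$histology$group)

summaries <- list()
for (nm in names(endpoints)) {
  g <- endpoints[[nm]]
  ks_p <- vapply(g, function(v)
    ks_normality(v, n_null = 2000, seed = seed)$p_value, numeric(1))
  ch <- group_chain(g, alpha = 0.05)
  message(sprintf(
    "%s: min normality p %.3g | KW chi-square %.2f, p %.3g",
    nm, min(ks_p), ch$kw$statistic, ch$kw$p_value))
  sig <- ch$pairwise[ch$pairwise$significant, ]
  if (nrow(sig))
    message("  significant pairs: ",
            paste(sig$group1, "vs", sig$group2, collapse = ", "))
  summaries[[nm]] <- list(
    normality_p = as.list(ks_p),
    kw = list(statistic = ch$kw$statistic, df = ch$kw$df,
              p_value = ch$kw$p_value),
    pairwise = as.data.frame(ch$pairwise),
    box = do.call(rbind, lapply(g, box_summary)))
}
jsonlite::write_json(summaries, "results/stats/group_stats.json",
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
message("wrote results/stats/group_stats.json")
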
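# hrvpipe

Time-domain heart-rate-variability analysis, nigrostriatal histology
densitometry, and nonparametric group statistics for a four-group rat
neurotoxin cohort — implemented as a tested R package plus a set of
numbered analysis drivers, and driven end to end by a synthetic-data
module so that every stage can be verified against known ground truth
without any recordings.

The package is aimed at researchers quantifying cardiac dysautonomia in
rodent models of Parkinson-like nigrostriatal degeneration (bilateral
striatal 6-OHDA lesions), where the endpoints are ECG-derived heart
rate and variability, tyrosine-hydroxylase (TH) immunoreactivity in the
substantia nigra pars compacta (SNc) and striatum, and body-weight
evolution.

## What it computes

**R-peak detection.** On a 1 kHz ECG, an R peak is a strict local
maximum (±10 ms) with amplitude above *mean + 0.7 SD* of the signal and
a 100 ms refractory distance between peaks; conflicting candidates
resolve by descending amplitude, ties to the earlier sample. Eight
one-minute stretches are selected from stationary sections of a record
(rolling 5 s window screen), the tachogram is built per stretch, and:

- HR = 60 / mean(RR)  [bpm]
- SDNN = sample SD of the R-R intervals  [s]
- RMSSD = √( Σ(RRᵢ₊₁ − RRᵢ)² / (N−1) )  [s]

The pooled R-R distribution is characterized by its four moments, with
skewness m₃/m₂^{3/2} and **non-excess** kurtosis m₄/m₂² (Gaussian = 3)
from biased central sample moments.

**Moment-matched simulation.** A Johnson translation system
(X = ξ + λ·g((Z−γ)/δ), g ∈ {id, exp, sinh, logistic}) is fitted to any
feasible (mean, SD, skewness, kurtosis) target — including
near-boundary and heavy-tailed rows — and sampled reproducibly, with a
documented 0.05 s positivity floor and reported clip counts.

**Histology.** Striatal optical density OD = mean log₁₀(I_bg / I) with
the background estimated from the brightest decile of the ROI; SNc
nuclei counted by Otsu threshold → 8-connected components → area
filter; percent reduction = 100·(1 − mean(group)/mean(control)).

**Statistics.** Monte-Carlo Lilliefors normality screen,
Kruskal–Wallis with midranks and tie correction, Dunn's pairwise rank
comparisons with Bonferroni correction (α = 0.05), and notched-boxplot
summaries (notch half-width 1.57·IQR/√n).

## Worked example

Simulate a sham-like rhythm, render an ECG, and recover the metrics:

```r
library(hrvpipe)

rr  <- simulate_rr_series(rr_process_params(0.177, 0.0086,
                                            model = "ar1", ar1_rho = 0.65),
                          n = 330, seed = 3)
ecg <- synthesize_ecg(rr, ecg_synth_params(noise_sd = 0.04), seed = 4)
pk  <- detect_r_peaks(ecg)                 # mean + 0.7 SD, 100 ms spacing
tg  <- build_tachogram(pk)
hrv_metrics(tg)
#> # A tibble: 1 x 7
#>   animal_id group  epoch hr_bpm  sdnn_s rmssd_s n_beats
#>   <chr>     <chr>  <int>  <dbl>   <dbl>   <dbl>   <int>
#> 1 NA        NA        NA   338. 0.00858 0.00767     331
```

HR ≈ 338 bpm and SDNN ≈ 0.0086 s recover the simulated rhythm (mean
R-R 0.177 s, marginal SD 0.0086 s); RMSSD < √2·SDNN reflects the
positive lag-1 correlation of the AR(1) process.

Fit a distribution to a printed moment row and round-trip it:

```r
spec <- fit_moment_matched(moment_set(0.1467, 0.0072, 1.5494, 3.4277))
spec$family                        # "sb" -- 0.027 above the feasibility bound
x <- sample_dist(spec, 1e6, seed = 1)
unlist(unclass(distribution_moments(x)))
#>        mean          sd    skewness    kurtosis
#> 0.146702844 0.007202177 1.548109765 3.423668738
```

The numbered drivers under `analysis/` run the full study on synthetic
data — `01_simulate.R` (inputs with ground truth), `02_ecg_hrv.R`
(detection → tachograms → HRV), `03_histology.R` (counts, OD, percent
reductions), `04_group_stats.R` (statistical chain) and `05_report.R`
(end-to-end bundle with manifest) — writing their tables under
`results/`. A run with the default seed counts 117 nuclei against a
ground truth of 117 in the lesion image (53.2 % reduction vs control,
scenario truth 53.38 %) and measures a 24.1 % striatal OD reduction
against a rendered 25 % fiber deficit.

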
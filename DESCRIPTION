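Package: hrvpipe
Title: Heart Rate Variability, Nigrostriatal Histology Densitometry, and
    Nonparametric Group Statistics for Rat ECG Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, synthetically testable pipeline for a
    four-group rat neurotoxin cohort: amplitude-threshold R-peak detection
    on 1 kHz ECG with stationary-epoch selection, tachogram construction,
    time-domain heart rate variability metrics (HR, SDNN, RMSSD) and
    R-R distribution moment analysis (skewness, non-excess kurtosis),
    Johnson-system moment-matched R-R simulation, tyrosine-hydroxylase
    histology quantification (striatal optical density, substantia nigra
    nuclei counts, percent reduction versus control), weekly body-weight
    trajectories, and the Kruskal-Wallis / Dunn-Bonferroni statistical
    chain with notched-boxplot summaries. Every stage is driven by a
    synthetic-data module with known ground truth, so the whole pipeline
    is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
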
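---
title: "Methods: synthetic-cohort HRV and histology quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-cohort HRV and histology quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvpipe)
```

## Scope and model of the pipeline

`hrvpipe` implements the computational chain of a four-group rat
neurotoxin study of cardiac dysautonomia and nigrostriatal damage:
groups `sham`, `sham_p`, `ohda` (striatal 6-OHDA lesion) and `ohda_p`
(lesion plus a nutritional intervention). The measured endpoints are
time-domain heart-rate variability from 1 kHz ECG, tyrosine-hydroxylase
(TH) staining quantified on micrographs, and weekly body weight. No raw
recordings ship with the package; instead a synthetic-data module
generates every input with known ground truth, which is what makes each
stage testable end to end.

### R-peak detection and epoching

A peak is a strict local maximum over a ±10 ms neighbourhood (plateaus
resolve to their first sample) whose amplitude exceeds

$$\bar{x} + 0.7\,s_x,$$

the signal mean plus 70% of its standard deviation, with a minimum
distance of 100 ms between accepted peaks. Among candidates competing
inside the refractory gap, the larger amplitude wins and ties go to the
earlier index; the returned set satisfies the minimum gap by
construction, and the whole rule is invariant to positive rescaling of
the trace because the threshold is affine in the signal's own mean and
SD. The threshold statistics are computed per analysed stretch by
default (`threshold_scope = "per_epoch"`), since the metrics are
reported per one-minute stretch; a whole-record scope is available. No
pre-filtering is applied by default.

Eight one-minute stretches are selected from stationary sections. The
stationarity screen is the package's own construction (only "stationary
sections" is specified by the protocol it follows): the record is tiled
into rolling 5 s windows, and a stretch qualifies when (a) the
coefficient of variation of its window SDs is at most 0.5 and (b) its
median window SD lies within a factor 2 of the record-wide median. The
level condition (b) exists because a stretch that is uniformly noisy —
say ten times the variance of the rest of the record — is internally
"stationary" by criterion (a) alone, yet is exactly the kind of section
the selection is meant to avoid. Both thresholds are exposed in
`epoch_plan()`.

### Time-domain HRV and distribution moments

From the tachogram (successive R-R intervals in seconds):

- HR $= 60/\overline{RR}$ beats·min⁻¹, per stretch;
- SDNN $=$ sample SD of the intervals ($N-1$ denominator), seconds;
- RMSSD $= \sqrt{\tfrac{1}{N-1}\sum_{i=1}^{N-1} (RR_{i+1}-RR_i)^2}$,
  seconds.

Distribution shape uses biased central sample moments:
skewness $= m_3/m_2^{3/2}$ and kurtosis $= m_4/m_2^{2}$ in the
**non-excess** convention (a Gaussian has kurtosis 3); this is the
convention of the numerical environments these analyses are usually run
in, and a `bias_correct` flag switches to the adjusted estimators. The
statistical unit for group comparisons defaults to the stretch (one row
per epoch per animal), with per-animal means emitted alongside for
sensitivity analysis.

### Moment-matched R-R simulation (Johnson system)

The scenario moment table the simulator reproduces contains a row only
0.027 above the kurtosis feasibility bound
($\beta_2 \ge \beta_1 + 1$) and a row with kurtosis 15.3, so the
moment-matching family must cover the whole
$(\text{skewness}^2, \text{kurtosis})$ plane. The package uses the
Johnson translation system
$X = \xi + \lambda\, g\!\left((Z-\gamma)/\delta\right)$ with
$g = \operatorname{id}, \exp, \sinh, \operatorname{logistic}$ for the
normal, lognormal (SL), unbounded (SU) and bounded (SB) families. The
family is selected by position relative to the lognormal line; shape
parameters $(\gamma, \delta)$ are solved by multi-start Nelder–Mead on
$(\gamma, \log\delta)$ against the closed-form SU/SL moments or
adaptive-quadrature SB moments; $\xi, \lambda$ then match mean and SD
exactly. Fits are accepted only when implied skewness and kurtosis are
within $10^{-3}$ of the target (in practice the residual is near
machine precision, including for the boundary-adjacent row, which lands
in SB with $\delta \approx 0.014$ — a nearly two-point distribution, as
the feasibility boundary demands).

Sampling is a quantile transform of `rnorm`, bit-reproducible for a
fixed seed. R-R samples are clipped below at **0.05 s** — no protocol
statement covers nonphysiological intervals, so the package picks a
floor far below any plausible rat R-R and always reports the clip
count rather than silently altering data. The fitted bounded supports
of the scenario rows lie above the floor, so in practice the count is
zero there; for unbounded (SU) rows a handful of draws per million can
clip.

### Synthetic ECG

The ECG generator stamps a QRS-like template (biphasic Gaussian lobe
pair by default, Ricker wavelet as an alternative; amplitude 1 mV,
width 12 ms) at the cumulative beat times of a supplied R-R series,
adds optional 0.5 Hz sinusoidal baseline wander and white noise, and
quantizes to 1 µV. `ground_truth_beats` holds the rendered R-wave
maxima, so detector recall/precision can be scored exactly; at zero
noise the detector must recover the truth sample-for-sample. An empty
R-R series yields the single initial beat (beat times are
`cumsum(c(0, rr))`) — a documented, tested convention. The waveform is
a fixture for exercising the detector, not a claim about rat ECG
morphology: there are no P/T waves and no respiratory modulation.

### Histology quantification

*Densitometry.* Per-pixel optical density is
$\mathrm{OD} = \log_{10}(I_{bg}/I)$ with the background $I_{bg}$
estimated from the brightest decile of the region of interest (the
"optical density" of the original ImageJ workflow is under-specified,
and cross-image illumination is uncontrolled, so a per-image background
reference is the defensible choice). Saturated-black pixels clip at an
OD ceiling of 3 with a reported count. The synthetic striatum images
follow the transmission law $I = I_0 10^{-a}$ with absorbance
proportional to `fiber_density`, which makes OD additive under stacked
layers and makes the percent-reduction recovery an exact linear check
up to noise and background-estimation bias.

*Counting.* SNc nuclei are segmented by Otsu threshold, labelled as
8-connected components, area-filtered (defaults 8–10⁵ px²), and
counted. A contrast guard treats images whose Otsu classes differ by
less than 20 gray values as unstained (count 0) so that pure noise is
not split into spurious objects. The synthetic SNc generator places
disks with centre separation at least $2r + 3$ px, so components are
disjoint and the count is unambiguous; no stereological correction is
applied, matching raw per-section counting.

### Group statistics

Normality is screened with a one-sample KS test against a normal with
estimated parameters; since estimation invalidates the textbook null,
the null distribution is built Lilliefors-style by seeded Monte Carlo
(default 10⁴ replicates, reusable across samples of equal size via
`ks_null_table()`). Group comparison is Kruskal–Wallis with midranks
and tie correction (delegated to `stats::kruskal.test`; an independent
textbook-formula oracle backs it in the tests), followed by Dunn's
pairwise rank comparisons with the pooled-rank variance, raw p values
multiplied by the number of pairs and capped at 1. The exact post hoc
machinery of the original workflow is unstated; Dunn-with-Bonferroni is
the standard reading of "Bonferroni post hoc" after Kruskal–Wallis, and
`group_chain()` gates pairwise flags on the omnibus test at
$\alpha = 0.05$. Notched box summaries use quartiles with linear
interpolation, notch half-width $1.57\,\mathrm{IQR}/\sqrt{n}$ and
fences at 1.5 IQR.

## What the generators emulate — and what they do not

The cohort scenario (group medians for HR/SDNN/RMSSD, nuclei deficits
of 53.38% and 28.12%, fiber-density deficits of 25% and 17.7%, weight
trajectories from day-0 and day-40 means and SDs, group sizes 6/5/5/5
for ECG, 3/4/5/5 for histology, 13/13/9/9 for weights) reproduces the
study conditions the package emulates. Between-animal heterogeneity is
a 4% coefficient of variation on the group HRV levels and 5%/2% on
nuclei counts and fiber density — values chosen once as plausible
biological spread, not fitted to anything. The AR(1) R-R model matches
marginal SD (SDNN scale) and successive-difference SD (RMSSD scale,
via $\mathrm{sd}_\Delta = \sigma\sqrt{2(1-\rho)}$) but not the true
spectral content of rat heart rate; the ECG template carries no QRS
morphology variation; micrographs have uniform illumination and
non-touching nuclei. Passing tests therefore demonstrate correctness
of the computations and recoverability of known ground truth under
controlled conditions — they do not validate the detector against
pathological morphologies, overlapping cells, or uneven staining in
real data.

One scenario row deserves note: the lesion group's printed R-R SD
(0.1675 s against a mean of 0.2415 s, a coefficient of variation near
70%) is implausibly large for rat R-R data and likely reflects pooling
of multimodal per-animal distributions. The simulator reproduces the
row as printed without interpreting it; the direct Gaussian R-R process
(`rr_process_params`) refuses such parameters because its feasibility
rule `mean - 4*sd > 0` would be violated, while the moment-matched
route represents the row faithfully through a bounded Johnson SB
distribution supported on (0.058, 0.79) s.

## Numerical choices

- Johnson SB moments use `stats::integrate` (rel. tol 10⁻¹²); SU, SL
  and normal moments are closed-form. The 2-D shape solve runs
  Nelder–Mead from a 9 × 5 start grid with polish restarts and accepts
  residuals below 10⁻¹⁰.
- Degenerate inputs: zero-variance R-R series yield SDNN = RMSSD = 0
  and flagged (`NA`) shape moments rather than fabricated values;
  constant traces detect no peaks (with a warning); constant samples
  are reported as degenerate by the normality screen with a
  below-machine-floor p value; identical groups give H = 0, p = 1.
- Ties: midranks with the standard tie correction everywhere;
  detection ties resolve to the earlier sample.
- Ectopic-interval filtering is off by default (no correction is part
  of the emulated protocol); the positivity floor at 0.05 s is the
  only alteration ever applied to simulated intervals, and it is
  counted and reported.
- Seeds are explicit arguments everywhere; `stage_seed()` fans a
  single global seed out to stages by fixed offsets, and report
  bundles are byte-identical across reruns of one seed.

## Problem sizes used by the test-suite

Moment round-trips run at 10⁶ draws per scenario row with tolerances
of three Monte-Carlo standard errors (batch-estimated for the shape
moments, closed-form for mean and SD). Detector-oracle equivalence uses
random traces up to 10⁴ samples; the type-I calibration of the full
Kruskal–Wallis + Bonferroni chain uses 10⁴ null replicates of four
groups of five; the counting check runs the full control-scale scenario
(996 nuclei, radius 4 px, 2048² frame) once and smaller cohorts
elsewhere. The bundled analysis scripts use a 9-minute demonstration
ECG and 512² micrographs — sizes chosen so a complete run stays
comfortably interactive while every statistical check retains its
stated power.

## Known limitations

- Frequency-domain and nonlinear HRV are out of scope, as is any QRS
  morphology classification.
- The OD definition is the package's own (per-image background
  reference); absolute OD values are not comparable to integrated
  densities from other workflows, though within-pipeline contrasts
  (percent reductions) are.
- The Monte-Carlo normality screen is exact only up to simulation
  error; with the default 10⁴ replicates the p value has a standard
  error of about 0.002 near p = 0.05.
- Printed group-level test statistics of the emulated study depend on
  raw recordings that were never deposited; the pipeline reproduces
  the methods and the printed distribution/scenario parameters, not
  those statistics.
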
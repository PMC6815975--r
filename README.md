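# qeegr

Quantitative EEG recovery analysis after cardiac arrest, in R.

After resuscitation from cardiac arrest, cortical activity recovers through
a stereotyped EEG sequence — isoelectric, burst suppression, continuous
background — whose timing and richness predict survival and neurological
outcome. `qeegr` implements the quantitative pipeline used to study this in
the rodent asphyxial model:

* a **synthetic cohort generator** producing seeded two-channel post-ROSC
  recordings with *planted* recovery dynamics (phase timelines, burst
  occupancy trajectories, survival and outcome variables) for two study
  arms, so every analysis stage is verifiable against ground truth;
* **preprocessing**: zero-phase 0.3–100 Hz Butterworth band-pass, 50 Hz
  notch (Q = 30), scheduled one-minute segment extraction (baseline, 5 min,
  then every 30 min post-ROSC) with artifact screening and ±60 s sliding;
* **pattern classification**: a cross-channel minimum amplitude envelope
  (half peak-to-peak, 0.5 s windows) drives burst detection (>10 µV, gaps
  <0.5 s merged) and a rolling-window three-pattern classifier, yielding the
  onset time of burst (**OTOB**) and time to normal trace (**TTNT**);
* **features**: per-segment burst-suppression ratio
  (BSR = burst time / segment time; higher = better recovery) and
  weighted-permutation entropy
  (WPE = −Σ p<sub>w</sub>(π) ln p<sub>w</sub>(π) / ln m!, variance-weighted
  ordinal patterns, m = 5, τ = 1), plus trapezoidal time-weighted averages
  **TWA-BSR** and **TWA-WPE** over the schedule;
* **statistics**: Kolmogorov–Smirnov-gated t / rank-sum group comparison,
  Spearman correlation with Fisher-z CIs, survival ROC/AUC (Mann–Whitney
  with tie half-credit, stratified bootstrap CI), and Kaplan–Meier curves
  with log-rank tests.

The methods vignette (`vignettes/qeegr-methods.Rmd`) documents the models,
parameter choices and limitations in detail.

## Worked example

```r
library(qeegr)

gen <- generatorConfig(nPerGroup = 20, fs = 250, seed = 1)
cohort <- generateCohort(gen)
prof <- cohort[1, ]
prof[, c("animalId", "plantedOtobMin", "plantedTtntMin", "twaBsrTarget")]
#>   animalId plantedOtobMin plantedTtntMin twaBsrTarget
#> 1    H2-01       21.39215        189.091     0.618774

rec <- generateRecording(prof, gen)          # 240 min, two channels
res <- analyzeRecording(rec, pipelineConfig(generator = gen))
res$timeline
#> PatternTimeline 'H2-01' over 239.994 min:
#>   [   0.00 -   21.39] isoelectric
#>   [  21.39 -  189.05] burst_suppression
#>   [ 189.05 -  239.99] continuous
round(c(res$otobMin, res$ttntMin, res$twaBsr), 4)
#> [1]  21.3859 189.0545   0.6153
```

The detected OTOB/TTNT sit within a fraction of a minute of the planted
boundaries, and the measured TWA-BSR within ~0.01 of the planted target —
this planted-truth recovery is exactly what the test suite checks at cohort
scale. A whole-cohort run with all output tables:

```r
run <- runPipeline(pipelineConfig(generator = gen), outDir = "results")
subset(run$stats, analysis %in% c("km_median_Ctrl", "roc_auc_twa_bsr"))
```

writes `cohort.csv`, `animals.csv`, `features.csv`, `timelines.bed`,
`stats.csv` and `run.log` (all stamped with the master seed and a config
hash; reruns are checksum-identical). A thin command-line wrapper lives at
`inst/scripts/qeeg-pipeline.R`.

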
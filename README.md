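# eegFatigueNet

Graph-theoretical analysis of EEG functional-connectivity changes between a
pre-task and a post-task (cognitively fatigued) state, for paired
resting-state study designs.

Sustained cognitive load changes both the spectral content of the EEG and
the phase-coupling structure between channels. This package implements the
full analysis chain used to characterize those changes on a 56-channel
10–20 montage, for researchers who have cleaned, paired resting-state
recordings and want band-power comparisons, phase-based connectivity
networks and topology statistics from a single reproducible pipeline.

## What it computes

**Spectral layer.** Welch PSD (2 s Hanning segments, 50 % overlap, mean
detrend) per channel; band power as the log10 density integral over
θ = [4, 8), α = [8, 13), β = [13, 30) Hz; whole-brain means by channel-wise
averaging.

**Connectivity layer.** Weighted phase lag index from the Hilbert
instantaneous phase of band-passed signals (4th-order Butterworth,
forward–backward). The default estimator is the magnitude of the
time-averaged sine of the phase difference,

    wPLI(i, j) = | Σ_k sin(Δφ_ij(k)) / N |,

with the conventional imaginary-part-weighted index available as
`estimator = "standard_wpli"`. Both are amplitude-invariant, live in [0, 1]
and suppress zero-lag (volume-conduction-like) coupling.

**Graph layer.** Proportional thresholding (strongest edges kept, weights
preserved) and weighted metrics with edge length 1/w: global efficiency
Eg = mean pairwise 1/d; characteristic path length Lp; Onnela clustering
Cp; local efficiency Eloc; small-world Sigma = (Cp/Cp_rand)/(Lp/Lp_rand)
against degree-preserving rewired surrogates; nodal efficiency NE and
degree centrality (strength) DC with means over ten named scalp regions.

**Statistics layer.** Normality-gated paired tests (Shapiro–Wilk or
Lilliefors gate; paired t vs Wilcoxon signed-rank), Cohen's
d = M_diff / S_diff, effect size r = d/√(d²+4) (Wilcoxon branch:
r = Z/√N), Bonferroni families (bands m = 3, global m = 5, local m = 10,
i.e. α′ = 0.0167 / 0.01 / 0.005 at α = 0.05) and Spearman correlation of
metric changes against subjective fatigue (VAS-F) changes.

**Synthetic cohorts.** A seeded generator of paired 56-channel recordings
with known band-power shifts and alpha-band phase-coupling structure plus
VAS-F scores, so the whole chain can be validated against ground truth. See
`vignettes/methods.Rmd` for every modelling choice and default.

## Worked example

```r
library(eegFatigueNet)

cfg    <- simulationConfig(nSubjects = 12, duration = 20, seed = 2024)
cohort <- simulateCohort(cfg)          # 24 recordings + VAS-F scores
report <- runStudy(cohort, studyConfig(nNull = 20, includeSweep = FALSE,
                                       seed = 2024))
print(report)
```

```
Study report
  selected band: alpha 
  band tests (alpha' = 0.0167 ):
  band     test        p     r significant
 theta paired_t 1.63e-03 0.513        TRUE
 alpha paired_t 1.96e-08 0.899        TRUE
  beta paired_t 1.90e-04 0.621        TRUE
  global metric tests (alpha' = 0.01 ):
 metric     test        p meanChange significant
     Eg paired_t 5.27e-05     0.0128        TRUE
   Eloc paired_t 1.26e-04     0.0230        TRUE
     Cp paired_t 3.53e-02     0.0221       FALSE
     Lp paired_t 1.25e-04    -0.8584        TRUE
  Sigma paired_t 2.24e-02    -0.0966       FALSE
  significant local changes (alpha' = 0.005 ): 
 metric          region        p
     NE  fronto-central 0.000261
     NE centro-parietal 0.003825
     DC  fronto-central 0.000650
     DC        temporal 0.000488
```

Reading the output: all three bands show a post-task power elevation, with
the alpha band carrying the largest effect size (r = 0.899 here), so alpha
is selected for network construction. On the alpha-band wPLI networks,
global and local efficiency rise and the characteristic path length falls
after the task — the brain network becomes more integrated — while the
small-world index does not survive its Bonferroni threshold. Nodal
efficiency gains are concentrated in anterior regions, where the synthetic
cohort injected its post-task cross-cluster coupling.

Lower-level entry points: `welchPsd()`, `bandPower()`, `bandSpectrum()`,
`connectivityMatrix()`, `proportionalThreshold()`, `globalMetrics()`,
`nodalMetrics()`, `thresholdSweep()`, `pairedTest()`, `dToR()`,
`bonferroni()`, `spearmanCorrelation()`; plain-text I/O via
`writeCohort()`/`readCohort()` and friends.

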
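---
title: "Methods: band power, wPLI networks and paired graph-metric statistics for pre/post cognitive-fatigue EEG"
author: "eegFatigueNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, wPLI networks and paired statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`eegFatigueNet` implements a complete analysis chain for paired (pre-task /
post-task) resting-state EEG studies of cognitive fatigue:

1. **Spectral layer** — Welch power spectral density per channel, band power
   for theta (4–8 Hz), alpha (8–13 Hz) and beta (13–30 Hz), and whole-brain
   (channel-wise mean) band powers per subject and condition.
2. **Connectivity layer** — band-pass filtering, Hilbert instantaneous
   phase, and weighted phase lag index (wPLI) connectivity over all unique
   pairs of a 56-channel 10–20 montage.
3. **Graph layer** — proportional thresholding and weighted topology
   metrics: global efficiency (Eg), local efficiency (Eloc), clustering
   coefficient (Cp), characteristic path length (Lp), small-world Sigma,
   nodal efficiency (NE) and degree centrality (DC, node strength), with
   region-level aggregation over ten named scalp regions.
4. **Statistics layer** — normality-gated paired tests (paired t or
   Wilcoxon signed-rank), Cohen's d and effect-size r with the conversion
   r = d/sqrt(d^2 + 4), Bonferroni families, and Spearman correlation of
   metric changes against subjective fatigue (VAS-F) changes.
5. **Synthetic-data layer** — a seeded generator of paired 56-channel
   cohorts with known band-power and phase-coupling ground truth, used to
   validate the whole chain end to end.

The pipeline assumes **cleaned** input: artifact rejection, re-referencing,
bad-channel interpolation and ICA-based artifact removal are upstream,
out-of-scope steps. Input is accepted as delimited channels-by-samples
matrices with a JSON metadata sidecar (`readRecording()`/`readCohort()`);
no binary EDF reader is bundled.

# The spectral model

`welchPsd()` averages periodograms over mean-detrended, Hanning-tapered
segments with 50% overlap. Two numerical choices are not dictated by the
procedure itself and are fixed here:

* **Segment length: 2 s** (1000 samples at 500 Hz), giving 0.5 Hz
  resolution. This resolves the 4 Hz theta edge while leaving ~180 averaged
  segments in a 3-minute record, a good bias/variance point for resting EEG.
* **Log scale**: band powers are reported as `log10` of the density integral
  over the half-open interval `[lo, hi)`. Whole-brain means on this scale are
  negative for weak bands and directly comparable across subjects after any
  common amplitude rescaling (a gain change shifts all values by a constant).
  Half-open intervals make the shared band edges (8 Hz, 13 Hz) unambiguous:
  an edge belongs to the upper band.

The Parseval identity (density integral = variance) and the
decreasing-variance property across segment counts are asserted in the test
suite rather than claimed here.

# wPLI: two estimators, one default

The study's printed connectivity definition is

$$\mathrm{wPLI}(i,j) = \left| \frac{1}{N}\sum_k \sin\!\big(\Delta\phi_{ij}(k)\big) \right|,$$

the magnitude of the time-averaged sine of the instantaneous phase
difference. This is **not** the conventional weighted phase lag index (which
weights by the magnitude of the imaginary cross-spectrum); it is closer to a
rectified phase-lag statistic. Because the textual name and the printed
formula disagree, both are implemented:

* `estimator = "paper_formula"` (default): exactly the formula above, on
  unit phasors of the Hilbert phase;
* `estimator = "standard_wpli"`: |E[Im X]| / E[|Im X|] with
  X = amplitude-weighted cross-spectral terms.

Neither is asserted to be "what the original study ran"; the default follows
the printed equation. Both are amplitude-invariant (exactly for the phase
formula; by ratio cancellation for the standard index), both are bounded in
[0, 1], and both vanish for strictly zero-lag coupling — the property that
suppresses volume-conduction artifacts.

Filtering uses a 4th-order Butterworth applied forward-backward (zero
phase); one second of samples at each end is excluded from phase statistics
as filter transient. The index is computed over the full continuous record
(a single sum over time points), not epoch-averaged, matching the printed
single-sum form.

# Graph metrics

All metrics are **weighted**; matrices are never binarized. The printed
group-level magnitudes (Lp near 7–8, DC near 1.5–2.3 on 56 nodes) are
consistent with weighted metrics on wPLI-scale weights and inconsistent with
binary conventions, which fixes this otherwise open choice.

* Edge length for shortest paths is `1/weight` (strong coupling = short
  functional distance). Disconnected pairs contribute 0 to efficiencies and
  are excluded from Lp.
* Cp uses the Onnela geometric-mean triangle form with weights normalized by
  the network maximum, averaged over all nodes (degree < 2 contributes 0).
* Eloc is the mean over nodes of the global efficiency of each node's
  neighborhood subgraph (Latora–Marchiori).
* Sigma = (Cp/Cp_rand)/(Lp/Lp_rand) against degree-preserving
  Maslov–Sneppen rewired surrogates carrying the original weight multiset;
  100 surrogates by default, seeded. An Erdős–Rényi graph then scores
  Sigma ≈ 1 and a mildly rewired ring lattice scores Sigma > 1 (both are
  test-suite properties).
* Proportional thresholding keeps exactly `round(p · n(n−1)/2)` strongest
  edges; ties break lexicographically so the selection is reproducible.

The statistics are computed at a **single retention proportion, default
0.25**. Whether the original analysis tested one proportion or integrated
across its sweep is not derivable from the text; the sweep
(`thresholdSweep()`, default 0.10–0.50 in 0.05 steps) is exposed for the
threshold-dependence curves, and the per-proportion default is the
conventional mid-sparsity operating point.

# Statistics layer

* Band comparisons are gated by a Lilliefors (Kolmogorov–Smirnov with
  estimated parameters) normality test; graph metrics by Shapiro–Wilk —
  matching the respective sections of the study design. The gate decides the
  branch (paired t vs Wilcoxon signed-rank) as a pure function; there is no
  silent fallback.
* Regions with 3 or fewer channels skip the gate ("not evaluated") and are
  tested nonparametrically, mirroring the small-sample omission rule.
* Parametric effect size: d = mean(diff)/sd(diff), converted by
  r = d/sqrt(d^2+4). Nonparametric: r = Z/sqrt(N). The literal printed form
  r = Z/N cannot produce effect sizes of the reported magnitude; the
  conventional Z/sqrt(N) is the default and the literal form is available
  via `literalR = TRUE` for audit.
* Wilcoxon uses the exact distribution for fewer than 20 untied non-zero
  differences and the tie-corrected normal approximation with continuity
  correction otherwise. All tests are two-sided.
* Bonferroni families: bands m = 3 (alpha' = 0.0167), global metrics m = 5
  (alpha' = 0.01), local metrics m = 10 (alpha' = 0.005). The local family
  size follows the printed threshold 0.05/0.005 = 10, i.e. one family per
  metric across the ten regions.
* The "total VAS-F score" entering the fatigue correlation is not defined in
  the source; the package uses the **change in the fatigue subscale**
  (post − pre), the subscale that defines the fatigue endpoint.

# What the synthetic generator emulates

`simulationConfig()` defaults define the validation conditions:

* 48 subjects, 500 Hz, 180 s records, 56-channel montage, 1/f background
  noise (slope beta = 1, typical of resting EEG), per-channel amplitudes
  randomized ±20% to exercise amplitude invariance of the phase metrics.
* **Band powers.** Oscillators are narrow-band Gaussian noise (raised-cosine
  spectral skirts inside the nominal band edges), not sinusoids, so the
  instantaneous phase is nondegenerate. Pre-task variances follow eyes-open
  resting EEG (alpha strongest); post/pre ratios equal the printed
  whole-brain log10 shifts: theta +0.335, alpha +1.338, beta +0.124.
  Between-subject common gain SD = 1.0 log10 units reproduces the printed
  between-subject spread; within-subject per-band jitter SD = 0.22 log10
  units makes the paired Cohen's d approximately 4.3 / 1.1 / 0.4 for
  alpha / theta / beta — the printed ordering with alpha dominant.
* **Coupling.** Six alpha-band clusters (frontal, fronto-central, central,
  centro-parietal = targeted; parietal and occipital/parieto-occipital =
  controls) share narrow-band carriers at mixing strength 0.65, with the
  m-th channel of a cluster lagging its carrier by (m−1)·0.9 rad (0.9 keeps
  all pairwise lags away from multiples of pi, where sine-based coupling is
  invisible). Post-task, the four targeted clusters additionally mix a
  common anterior master carrier (mixing 0.15 pre to 0.65 post). The post
  effect is therefore **cross-cluster integration** — shorter functional
  paths and richer triangles among anterior regions — rather than a change
  in within-cluster connection strength; this targets the dissociation in
  which path-based metrics (NE, Eg, Lp) move strongly while nodal strength
  (DC) moves little. Per-subject-condition cluster-strength jitter
  (SD = 0.15, multiplicative) supplies realistic between-recording
  connectivity variability.
* **VAS-F** scores are drawn at the printed subscale means/SDs on a 0–100
  scale (the printed magnitudes, although the scale is described as 10 cm;
  the magnitudes win because they are the quantities being emulated),
  clamped to [0, 100].
* `effect = FALSE` collapses every post parameter onto its pre value,
  giving a no-effect cohort for type-I-error checks with all
  within-subject variability retained.

**What it does not emulate:** volume conduction and field spread (no head
model), artifacts (blinks, EMG), event-related structure, non-stationarity
within a recording, or spatially correlated background noise. Passing
end-to-end tests therefore demonstrates that the analysis chain recovers
known spectral and phase-coupling structure at realistic SNR and sample
sizes — not that it is robust to the artifact structure of real recordings.

# Determinism and seeding

All randomness flows from integer root seeds through deterministic
substreams: each (subject, condition) recording, each VAS-F draw and each
Sigma null ensemble derives its own seed, so a cohort is bit-identical for
an identical configuration and recordings are identical whether simulated
alone or inside a cohort. Sigma null generation saves and restores the
global RNG state.

# Validation problem sizes

The shipped test suite validates the chain at reduced problem sizes chosen
for tight feedback loops: end-to-end recovery uses replicate cohorts of 24
subjects with 15-second 500 Hz records, 10 Sigma surrogates and 10 replicate
cohorts per arm; the shortest-path oracle fuzz covers 500 random graphs of
up to 12 nodes against a Floyd–Warshall reference; analytic wPLI cases use
10^4-sample phase series. The full study defaults (48 subjects, 180 s, 100
surrogates) remain the package defaults for real use.

# Known limitations

* The montage's prefrontal region is stored verbatim as F1/FZ/F2, which
  also belong to the frontal region (almost certainly intended as the FP
  series in the source tables); `montageOverlaps()` surfaces this rather
  than guessing a correction. Five of the 56 channel identities are
  inferred standard 10–20 names (FP1, FPZ, FP2, FT7, FT8) not enumerated in
  any table.
* Under weighted proportional thresholding, nodal strength (DC) and nodal
  efficiency (NE) are strongly collinear: most injected coupling increases
  move both. The master-carrier design above deliberately separates them
  (paths change, strengths much less), but a perfect "NE significant, DC
  not" dissociation at every sample size is not guaranteed by construction.
* The printed alpha-band effect size appears twice with different values
  (d = 4.23 in the spectral results; d = 1.10 in the band-comparison
  passage); both conversions are reproduced by `dToR()`, and the package
  takes no position on which describes the underlying contrast.
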
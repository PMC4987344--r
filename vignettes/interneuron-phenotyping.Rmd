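---
title: "Phenotyping piriform-cortex interneurons: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping piriform-cortex interneurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`apcephys` re-implements, as a tested pipeline, the intrinsic-physiology
phenotyping of anterior piriform cortex (APC) interneurons and the analysis
of optogenetically evoked inhibitory currents onto pyramidal cells. Because
no recordings are distributed with this kind of study, the package is built
around a synthetic-data generator: every analysis stage (feature
extraction, clustering, IPSC quantification, group statistics, anatomy
metrics) can be exercised and validated against generator ground truth.
This vignette documents the models, the calibration, the numerical choices,
and what the passing tests do and do not establish about real data.

## The membrane model

The generator's current-clamp substrate is a single-compartment adaptive
leaky integrate-and-fire neuron — the simplest model able to express the
three response motifs the phenotyping relies on: sag, spike-frequency
adaptation, and stuttering.

State variables: membrane potential $V$, sag activation $s$, adaptation
current $w$, threshold-gating process $x$, and an Ornstein–Uhlenbeck (OU)
background current $u$. Between spikes,

$$C\,\dot V = -g_L\,(V - E_L) \;+\; g_s\, s\,(E_h - V)\;-\;w\;+\;I(t)\;+\;u(t),$$
$$\tau_s\,\dot s = \frac{E_L - V}{E_h - E_L} - s,\qquad
  \tau_w\,\dot w = -w,\qquad
  \tau_x\,\dot x = -x + \sqrt{2\tau_x}\,\xi(t).$$

* **Sag (Ih-like) mechanism.** $s$ is a linearised activation that grows
  when the cell is hyperpolarised below rest and carries the depolarising
  current $g_s\,s\,(E_h - V)$ ($E_h = -30$ mV). During a hyperpolarising
  step the membrane initially deflects with the instantaneous resistance
  $R_0 = 1/g_L$ and relaxes toward the steady-state resistance
  $R_{ss} \approx 1/(g_L + g_s)$ — the classic sag.
* **Adaptation.** Each spike increments $w$ by $b$ pA; $w$ decays with
  $\tau_w$. This produces lengthening interspike intervals (adaptation
  ratio > 1) and caps sustained firing rates.
* **Stuttering.** A slow rectified threshold modulation: spikes occur when
  $V \ge V_{th} + a\,\max(x, 0)$ with $a$ in mV. When the slow OU process
  $x$ is positive, excitability is gated down and firing pauses; when it
  returns below zero the cell resumes tonic firing. Rectification is
  deliberate: it leaves subthreshold sweeps and the rheobase untouched
  (a bidirectional modulation lets the threshold dip below its nominal
  value, which both fires cells spontaneously at rest and — because
  rheobase is a minimum over many sweeps — collapses the measured
  rheobase of stuttering cells by an extreme-value effect). Every preset
  carries an amplitude as its irregularity knob, calibrated against the
  class CV_ISI: a few mV for "tonic" presets, large (tens of mV, a hard
  gate) for "stuttering" presets.
* **Noise.** $u$ is an OU current (1 ms correlation time) scaled so the
  stationary subthreshold voltage fluctuation equals `noise_sd` (0.1–0.3 mV
  across presets; deliberately small, since the sag measure reads a
  windowed extremum whose noise-induced bias grows with fluctuation
  amplitude).
* **Spike shape.** Integrate-and-fire dynamics carry no waveform, but the
  pipeline must measure spike width, so a stylised Gaussian waveform
  (threshold base, +30 mV peak) is stamped at each spike time; its scale is
  chosen in closed form so the measured full width at half height equals
  the configured `spike_shape_halfwidth`.

**Integration.** Fixed step at the 0.1 ms sampling interval. The voltage
uses an exponential-Euler update (exact for the passive subsystem, so the
pure-RC limit reproduces the analytic charging curve to rounding error);
the slow states use exact exponential decay and the OU processes their
exact discrete transition. Sample $k$ of a step segment corresponds to the
analytic solution at $t = k\,\Delta t$ after segment onset.

## Feature extraction conventions

Eight intrinsic properties per cell, from two step protocols
(−50…+50 pA in 10 pA increments, and 0–1000 pA in 100 pA increments; 1 s
steps, 10 kHz sampling):

| feature | convention |
|---|---|
| $R_{in}$ | OLS slope of steady-state deflection (mean of last 100 ms of the step minus pre-step baseline) vs current, −50..+50 pA; sweeps containing spikes are excluded |
| $\tau_m$ | monoexponential fit of the falling phase of the −50 pA response; window from onset to the trough of a 2 ms-smoothed copy, at least 8 ms, at most 5 initial-guess time constants; $\tau$ bounded in [0.1, 500] ms |
| sag | steady value (last 100 ms) minus the onset extremum: minimum of a 10 ms boxcar-smoothed copy within the first 50 ms |
| rheobase | smallest amplitude with ≥ 1 spike during the step; the subthreshold series is pooled with the suprathreshold series, so low-rheobase cells resolve on the 10 pA grid |
| spike width | mean full width at half height at the rheobase sweep; half-height is the midpoint of the spike peak and the detection-threshold crossing (0 mV); flank crossings linearly interpolated |
| max firing rate | max over sweeps of spike count ÷ step duration |
| AR | last ISI ÷ first ISI on the sweep 100 pA above rheobase |
| CV_ISI | sample SD ÷ mean of the ISIs on that sweep |

Choices worth flagging:

* **Onset extremum, not mean.** The sag onset value uses the smoothed
  extremum within the first 50 ms; a plain mean would dilute the transient,
  and a raw (unsmoothed) minimum would carry a noise bias of several times
  the noise SD. The 10 ms boxcar keeps that bias below ~0.05 mV at the
  generator's noise levels. Residual bias is absorbed by calibration.
* **Slow membranes leak charging into "sag".** For $\tau_m \gtrsim 15$ ms
  the membrane has not finished charging within the 50 ms onset window, so
  part of the measured "sag" of a slow cell is charging shortfall rather
  than Ih relaxation. The extraction implements the windowed definition
  as stated; the generator's sag conductance is calibrated against the
  *measured* value, so the convention is applied consistently on both
  sides.
* **Rheobase pooling.** The high-input-resistance class (G42-APC) has a
  published mean rheobase of ~71 pA, unreachable on a pure 100 pA grid
  (the smallest nonzero step is 100). Pooling the fine −50..+50 pA series
  resolves sub-100 pA rheobases and makes that calibration target
  attainable; cells whose threshold lies above +50 pA still land on the
  coarse grid.
* **Spikes invalidate, never abort.** Each feature fails soft: a missing
  protocol, a spiking −50 pA sweep, or < 2 ISIs yields an invalid flag on
  that feature; `extract_features()` always returns the full vector.
* If rheobase + 100 pA is not an available amplitude, the smallest
  available amplitude above it (or the highest sweep) is used and the
  substitution is flagged.

## Presets and calibration

Each interneuron class is a preset parameterised by physiological knobs
(steady-state $R_{in}$, sag depth, $\tau_m$, continuous threshold current,
spike half-width, refractory period, adaptation increment, noise and
stutter settings) mapped to mechanistic parameters in closed form.
Populations draw per-cell knobs by mean-preserving lognormal jitter whose
coefficients of variation are set from the published population standard
errors (SD ≈ SE·√n), with deviates truncated at ±2 SD: real cells occupy
a physiological range, and untruncated lognormal tails produce singleton
outlier cells that no recorded cohort shows and that derail a two-cluster
Ward cut.

Knob centres were calibrated by fixed-point iteration: simulate ~150
cells, extract features with the package's own pipeline, move each knob
toward its class target, repeat; the frozen centres live in the preset
registry. Calibration is against the *extracted* means, so extraction
biases (trough-window attenuation of sag, grid quantisation of rheobase,
fit-window effects on $\tau_m$) are compensated rather than ignored.
Achieved values for the classes used by the acceptance checks (n = 200,
fresh seed) sit within two published standard errors for the subthreshold
trio, the maximum firing rate, and CV_ISI of the tonic class; the
adaptation ratio of the stuttering presets is biased high (a pause falling
at the end of a sweep inflates the last ISI) and is the one systematic
residual — `analysis/02_extract_features.R` prints the full achieved
table for the shipped cohort.

The classification cohort mirrors the recorded composition: 14 SST-line
fast-spiking cells (3 stuttering) and 11 PV-line cells (3 tonic). The
tonic/stuttering variants of a line share subthreshold calibration and
differ only in the gating amplitude.

## IPSC simulation and decomposition

Light-evoked compound IPSCs are outward-positive currents at 0 mV: each
cell's inhibition is a somatic and a dendritic (L1B) component, each a
train of peak-normalised difference-of-exponential events inside the 20 ms
light window (somatic: 1/15 ms rise/decay; dendritic: 3/25 ms, delayed
1.5 ms). Local gabazine suppresses the targeted component to a residual
fraction; application at both sites suppresses both. Measurement:
trial-average, subtract the 100 ms pre-stimulus baseline, integrate the
positive current over 0–500 ms (trapezoid), keep averaged IPSCs with peaks
≥ 10 pA, and decompose

$$\text{other} = \frac{Q_{both}}{Q_{base}},\quad
  \text{somatic} = \frac{Q_{base}-Q_{soma}}{Q_{base}},\quad
  \text{distal} = \frac{Q_{soma}-Q_{both}}{Q_{base}},$$

which sum to 1 exactly. The default pyramidal-cell scenario uses a total
baseline charge of 40.6 pA·s, a dendritic fraction of 0.443 and a block
residual of 0.12: the noiseless decomposition then returns distal 39.0%,
somatic 48.7%, other 12.3%. The published per-cell estimates (distal
39 ± 7, somatic 43 ± 7, other ~8) do not satisfy the sum identity, so no
scenario can match all three simultaneously; the distal contribution — the
headline dendritic-inhibition result — is matched exactly and the somatic
value falls within its printed ±7. Per-cell variability (lognormal overall
strength with CV 0.55; dendritic split SD 0.08; residual SD 0.03) was
chosen a priori so that a six-cell cohort mean has a standard error of
~3 percentage points, treating the remainder of the printed spread as
measurement noise.

## Clustering workflow

Features are z-scored (sample SD), clustered with Ward's minimum-variance
method on Euclidean distances (the `ward.D2` formulation of
`stats::hclust`; merge heights are checked for monotonicity on every run),
and cut at a user-chosen k — the original workflow chose k visually, so no
automatic selection is provided. Sequential runs drop named groups and
recompute z-scores on the survivors, keeping a full audit trail. Benchmark
cells name the cluster they dominate (a majority tie is an error, never a
silent tie-break); known cells in a cluster named otherwise count as
misclassified. The test suite pins the implementation to an independent
brute-force agglomeration oracle (greedy minimum variance-increase from
raw coordinates) for n ≤ 7: merge heights agree as $\sqrt{2\,\Delta ESS}$
to machine precision.

## Statistics

The test-selection policy is a total, deterministic function of the
design: two groups with any n < 10 → Mann–Whitney U (unpaired) or
Wilcoxon signed-rank (paired); two larger groups → t-tests; more than two
groups → ANOVA with post-hoc Tukey under equal variances, Welch's ANOVA
for unequal variances with equal sizes, Kruskal–Wallis for unequal
variances and sizes. Variance homogeneity is assessed by Levene's test
(median-centred) at α = 0.05 — the original criterion is unstated, so this
is a documented package choice, as are two-sided defaults and the
linear-interpolation (type 7) quartile convention. Small-sample rank tests
use exact distributions; ties and zero differences are reported in the
result rather than silently dropped. MWU/WSR p-values are pinned to
exhaustive-permutation oracles in the tests.

## Anatomy module

Consumes point patterns / count tables / intensity patches, not raw
micrographs (commercial segmentation is out of scope): densities as
cells/mm² with section-then-animal averaging, co-labelling percentages
with an explicit denominator marker, and the L1B:L1A fluorescence ratio
from equal-area patches (scale invariant by construction). The generator
provides homogeneous Poisson patterns with independent marker labels and
Gaussian intensity patches; reporter-line presets encode the published
densities and co-label probabilities (SST line: 100 cells/mm², 75% SST⁺;
PV line: 48.2 cells/mm², 95% PV⁺; 0.83 mm² sections, ~40 reporter cells).

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; generation is bitwise
reproducible for a fixed seed. The replicate-cohort study uses 100 seeds
of 25 cells each; feature-recovery checks use 50-cell populations; the
IPSC cohort uses six cells of 10 trials — sizes chosen to match the study
design while keeping a full pipeline run in minutes on one core.

## What passing tests do and do not show

The generator emulates the *population statistics* of the recorded
classes (means and spreads of the eight features, IPSC charges and their
pharmacological structure), not raw-data pathologies: no electrode drift,
series-resistance error, seal degradation, truncated spikes, or
non-stationary excitability across sweeps. Passing calibration-recovery
tests therefore establishes that the extraction and classification code
implements its definitions correctly and recovers known ground truth under
realistic variability — not that the pipeline is robust to every artefact
of real recordings. Known limitations: the stuttering presets' adaptation
ratio runs high of its class mean (end-of-sweep pauses); "other" in the
IPSC decomposition is ~12% rather than ~8% (forced by the sum identity);
and G42-like cells' τ_m fits carry the trough-window convention's bias,
compensated by calibration rather than removed.
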
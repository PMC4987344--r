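# apcephys

Intrinsic-electrophysiology phenotyping and inhibitory-circuit analysis for
anterior piriform cortex (APC) interneurons.

## The problem

Somatostatin (SST) and parvalbumin (PV) interneurons in piriform cortex
cannot be told apart by eye: roughly two thirds of SST-line cells are
fast-spiking (FS), like PV cells. The workflow this package implements
distinguishes them quantitatively:

1. **Eight intrinsic properties** are extracted from current-clamp step
   protocols — input resistance *R*<sub>in</sub> (OLS slope of steady-state
   ΔV vs injected current over −50..+50 pA), membrane time constant
   τ<sub>m</sub> (monoexponential fit of the falling phase at −50 pA), sag
   (early-minus-late voltage difference of the −50 pA step, the
   I<sub>h</sub> signature), rheobase, spike width at half height, maximum
   firing rate, adaptation ratio AR (last/first interspike interval at
   rheobase + 100 pA) and CV<sub>ISI</sub> (SD/mean of those intervals).
2. **Ward hierarchical clustering on z-scores** (Euclidean distance,
   minimum-variance merges) classifies cells, with sequential re-clustering
   after removing identified groups and benchmark cells of known class to
   name the clusters.
3. **Optogenetically evoked IPSCs** are quantified as charge (pA·s, the
   area under the outward current at 0 mV), filtered at a 10 pA minimum
   amplitude, and decomposed into somatic, distal-dendritic (L1B) and
   residual contributions from local gabazine applications:
   `other = Q_both/Q_base`, `somatic = (Q_base − Q_soma)/Q_base`,
   `distal = (Q_soma − Q_both)/Q_base`.
4. **Small-sample statistics** follow a fixed test-selection policy
   (Mann–Whitney U / Wilcoxon signed-rank below n = 10; ANOVA–Tukey,
   Welch's ANOVA or Kruskal–Wallis for multiple groups, by variance
   homogeneity and group sizes), and **anatomy metrics** cover laminar
   densities (cells/mm²), co-labelling percentages and the L1B:L1A
   fluorescence ratio.

Because no recordings ship with a study like this, the package includes a
calibrated synthetic generator: an adaptive leaky integrate-and-fire
neuron with an I<sub>h</sub>-like sag conductance, spike-frequency
adaptation and a slow rectified threshold modulation that produces
stuttering. Presets reproduce the published population statistics of each
identified class (RS and FS SST-line cells, PV-line cells, GIN and G42
cells), so the whole pipeline is testable against ground truth. See the
methods vignette (`vignettes/interneuron-phenotyping.Rmd`) for models,
conventions and calibration details.

## Worked example

```r
library(apcephys)

# one synthetic fast-spiking SST cell, both step protocols
cell <- simulate_population("FS-SST-tonic", 1, seed = 1)[[1]]
extract_features(cell$sub, cell$supra)

# a mixed FS cohort (14 SST-like + 11 PV-like), clustered end to end
run <- classify_fs_cohort(seed = 1)
run$mis_8feat      # misclassified cells of 25, eight features
run$mis_3feat_sst  # misclassified SST cells, subthreshold trio only

# gabazine decomposition of one simulated pyramidal-cell experiment
ex <- simulate_pc_cohort(n = 1, seed = 1)[[1]]
measure_ipsc_experiment(ex)$decomposition
```

Output of the calls above:

```
           cell_id r_in tau_m   sag rheobase spike_width max_rate   ar cv_isi
1 FS-SST-tonic_001 91.6  4.26 0.378      500        0.44      171 1.63   0.14
```

— one draw from the fast-spiking SST population: input resistance in MΩ,
time constant in ms, sag in mV, rheobase in pA, spike width in ms, maximum
rate in Hz, plus the two interspike-interval statistics.

```
run$mis_8feat      # 8
run$mis_3feat_sst  # 6
```

Single 25-cell cohorts are noisy draws — misclassification ranges from 0
to ~10 across seeds; the stable quantity is the median over replicate
cohorts, which `fs_misclassification_study()` computes (median 4 of 25
with all eight features, median 2 misclassified SST-like cells with the
subthreshold trio, over 100 cohorts).

```
measure_ipsc_experiment(ex)$decomposition
# somatic 49.0%  distal 41.2%  other 9.8%
```

— the three-condition gabazine decomposition of one simulated cell:
roughly half of the pyramidal cell's inhibitory charge is blocked at the
soma, ~40% at the distal apical dendrite (L1B), and ~10% survives the
double block.

The `analysis/` scripts run the full study in order — simulate the cohorts
(`01`), extract and summarise features (`02`), run the staged clustering
and the replicate misclassification study (`03`), decompose pyramidal-cell
inhibition (`04`), and compute the anatomy statistics (`05`) — writing
their tables under `results/`.

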
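Package: apcephys
Title: Interneuron Phenotyping and Inhibitory Circuit Analysis for Piriform Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for intrinsic-electrophysiology
    phenotyping of anterior piriform cortex (APC) interneurons and for
    optogenetically evoked inhibitory currents. Provides an adaptive
    leaky integrate-and-fire membrane simulator with an Ih-like sag
    conductance, spike-frequency adaptation, and a slow stochastic
    stuttering mechanism; extraction of the eight standard intrinsic
    properties (input resistance, membrane time constant, sag, rheobase,
    spike width, maximum firing rate, adaptation ratio, CV of the
    interspike interval) from current-clamp sweep sets; z-scored Ward
    hierarchical clustering with sequential re-clustering and
    benchmark-cell labelling; IPSC trial averaging, charge quantification
    and pharmacological somatic/dendritic decomposition; the
    nonparametric test-selection policy used for small-sample group
    comparisons; and laminar cell-density, co-labelling and
    fluorescence-ratio statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    ape,
    minpack.lm,
    car
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
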
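Package: pvcircuit
Title: Functionally Specific Inhibitory Connectivity: Analysis Pipeline and
    Structured E/I Network Simulator
Version: 0.1.0
Authors@R:
    person("pvcircuit", "developers", email = "pvcircuit@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the relationship between in vivo visual
    responses and in vitro synaptic connectivity of parvalbumin-expressing
    (PV+) interneurons and pyramidal cells. Includes a seeded synthetic-data
    generator emulating trial-resolved calcium-imaging tensors and paired
    whole-cell recordings; fluorescence preprocessing (running-percentile
    detrending, Gaussian-mixture baseline estimation, 3-D affine registration);
    a constrained direction x spatial-frequency x temporal-frequency tuning
    model with responsiveness and selectivity statistics; pairwise response
    similarity metrics; PSP amplitude, paired-pulse and multiexponential
    kinetics quantification with geometric-mean normalization and a
    within-cell permutation test; and a structured recurrent
    excitatory/inhibitory spiking-network model (leaky integrate-and-fire
    neurons with alpha-conductance synapses) whose connection weights follow
    von-Mises-shaped tuning-similarity kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
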
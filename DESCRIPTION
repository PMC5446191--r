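Package: sorncrit
Title: Criticality Signatures in a Self-Organizing Recurrent Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a self-organizing recurrent network (SORN) of binary
    excitatory and inhibitory threshold units shaped by five interacting
    plasticity rules (spike-timing dependent plasticity, inhibitory STDP,
    synaptic normalization, structural plasticity and intrinsic homeostatic
    plasticity), and analyses the criticality signatures of its spontaneous
    activity: threshold-defined neuronal avalanches, discrete truncated
    power-law maximum-likelihood fits of avalanche duration and size,
    log-likelihood ratio model comparison, the crackling-noise scaling
    relation, frozen-plasticity and noise-regime experiments, external-input
    onset and readaptation, and two sequence-learning tasks (Counting Task
    and Random Sequence Task) with a linear readout trained by the
    Moore-Penrose pseudo-inverse.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
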
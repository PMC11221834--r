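Package: swrloop
Title: Closed-Loop Sharp-Wave Ripple Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for closed-loop hippocampal
    sharp-wave ripple (SWR) neurofeedback experiments. Provides a synthetic
    session generator (multi-tetrode LFP with injected ripple-band events,
    clusterless place-cell spike marks, 8-arm maze behavior), a streaming
    online SWR detector with iterative baseline and asymmetric envelope
    estimators, a consensus offline detector, a closed-loop task engine with
    threshold ramps and yoked delay controls, a clusterless state-space
    decoder over a linearized track graph, replay content classification
    with an arm-category Poisson GLM, and the behavioral statistics layer
    (rank-sum with Benjamini-Hochberg correction, mixed-effects group
    models, sign tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    lme4,
    lmerTest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
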
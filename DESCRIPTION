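Package: xmodal
Title: Single-Trial EEG Decoding and Neurally Informed Drift-Diffusion
    Modelling of Cross-Modal Congruency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how cross-modal associative congruency
    shapes perceptual decisions. Provides a synthetic-data generator for
    implicit-association-test sessions with multichannel EEG epochs and
    diffusion-generated behaviour; behavioural summaries with rank tests,
    Z/sqrt(N) effect sizes and subject-level bootstrap confidence
    intervals; epoch-level signal conditioning (zero-phase Butterworth
    filtering, anti-aliased downsampling, amplitude-based trial
    rejection); sliding-window single-trial discrimination of congruent
    versus incongruent trials with leave-one-out ROC performance,
    permutation significance thresholds and forward-model scalp
    projections; and a hierarchical drift-diffusion model in which
    single-trial EEG component amplitudes regress onto drift rate,
    decision boundary and non-decision time, fitted by adaptive
    Metropolis-within-Gibbs sampling with Gelman-Rubin diagnostics,
    posterior predictive checks and directional log-odds inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
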
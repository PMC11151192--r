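Package: somnaffect
Title: Sleep-Stage Suppression Analysis of Affective Responsivity and Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline analysis pipeline for selective sleep-stage
    suppression experiments relating sleep neurophysiology to affective
    responsivity and declarative memory. Provides hypnogram summaries,
    stage-episode segmentation and fragmentation indices; zero-phase FIR
    preprocessing of polysomnography EEG; individualized fast-spindle and
    slow-oscillation detection; slow-oscillation/spindle phase coupling with
    circular statistics; stage-specific accumulated spectral-energy measures;
    skin-conductance response computation; behavioural scoring of
    embarrassment ratings and cued metaphor recall; and linear mixed-model
    inference with repeated-measures covariance structures, Bonferroni
    follow-up families, nonparametric equivalents and sensitivity power
    analysis. A synthetic-data module generates suppression-condition
    polysomnography, electrodermal and behavioural cohorts with known ground
    truth so the whole pipeline is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nlme,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
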
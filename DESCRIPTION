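Package: selfreg
Title: Simulation and Modelling of Dietary Self-Control and Emotion
    Reappraisal Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the behavioural side of paired
    self-regulation experiments in which participants both reappraise
    emotional images and make incentivised food choices. The package
    simulates synthetic cohorts with known ground truth (taste/health
    rating profiles, tailored challenge-heavy choice sets, drift-diffusion
    choices and reaction times with a refusal-biased starting point, and
    SAM valence ratings), scores trials and participants (subjective food
    value, decision conflict, self-control stakes and their
    orthogonalisation, self-control and reappraisal success), fits a
    Wiener first-passage-time likelihood with censoring at the response
    deadline, and performs group-level association inference with
    bootstrap uncertainty, including end-to-end parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    boot,
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
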
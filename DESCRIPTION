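Package: motorpotential
Title: Latent Motor Potential in Saccadic Premotor Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing whether preparatory activity of
    premotor neurons carries a latent movement command ("motor potential").
    Implements detection of goal-directed saccades embedded in blink-perturbed
    eye movements via blink-related eye movement (BREM) velocity templates,
    across-trial lagged correlation between spike density and eye kinematics
    with efferent-delay estimation, trial-shuffled bootstrap significance,
    a non-parametric initiation-threshold analysis, and an accumulation-rate
    change analysis with surrogate pseudo-blink controls.  Includes a synthetic
    generator for the delayed saccade task with reflex-blink perturbations so
    that every stage of the pipeline is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
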
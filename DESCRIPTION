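Package: sleepgeom
Title: Population Geometry of Cortical Sound Representations Across Sleep and Wake
Version: 0.1.0
Authors@R:
    person("Sleepgeom", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large-scale calcium-imaging recordings of
    auditory cortex across wakefulness and NREM sleep: automated EMG/LFP sleep
    scoring with Gaussian-mixture thresholds, sigma-band spindle detection,
    trial-aligned response extraction, noise-ceiling-corrected representational
    similarity analysis, cross-validated PCA dimensionality with a circular-shift
    null, spontaneous/evoked subspace inclusion, balanced stimulus decoding, and
    bootstrap detection of coordinated population response failures. Ships a
    synthetic-session generator with full ground truth so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
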
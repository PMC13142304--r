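Package: tunedrift
Title: Orientation Tuning, Representational Drift, and Plasticity Scoring
    for Two-Photon Imaging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for quantifying orientation tuning and
    its stability across days from two-photon calcium imaging, together
    with the behavioral plasticity scores and immunostaining ensemble
    quantification that accompany such studies. Converts per-cell
    fluorescence traces to trial-evoked dF/F with skew-maximizing
    neuropil subtraction, fits Von Mises orientation tuning curves,
    measures fit reliability by trial-resampling bootstrap, quantifies
    representational drift of preferred orientation on the 180-degree
    circle, scores conditioned place preference, prepulse inhibition and
    novel object recognition sessions, and counts immunopositive cells
    with per-cell integrated densities from 2-D images. A synthetic-data
    generator with recorded ground truth drives verification of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
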
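Package: ccgrowth
Title: Single-Cell Growth Dynamics of Asymmetrically Dividing Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell growth dynamics in asymmetrically dividing
    bacteria such as Caulobacter crescentus, from tracked cell areas and
    replication-marker foci to cell-cycle-aligned growth-rate curves.
    Implements instantaneous and average growth-rate estimation from timelapse
    area trajectories, exponential-fit residual scoring, cell-cycle-unit
    alignment with bootstrap confidence bands and tempograms, G1-phase
    quantification from fluorescent focus counts under two cell-birth
    definitions (daughter-cell separation versus cytokinesis completion),
    rule-based swarmer/stalked progeny classification, trajectory curation
    filters with rejection logging, and diffraction-limited spot detection in
    labelled masks. A ground-truthed synthetic lineage and image generator
    reproduces the statistical structure the analysis assumes (G1-coupled
    growth slowdown, asymmetric division, cytokinesis preceding separation)
    so every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
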
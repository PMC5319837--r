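Package: spindle2d
Title: Cell-Shape-Based Prediction of Mitotic Spindle Position in Embryonic Blastomeres
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the position and orientation of the mitotic spindle in the
    apical plane of embryonic blastomeres from the 2D geometry of the cell
    outline, using a mechanical model in which astral microtubules radiating
    from each spindle pole pull on the cortex with forces that increase with
    microtubule length. Provides planar polygon and triangulated-mesh
    geometry (principal axes, ray casting, sphericity, apical-surface ratio,
    apical-plane extraction), deviation metrics comparing observed and
    predicted spindles, clone-pattern classification of oriented cell
    divisions, cell-cycle timing metrics, the distributional summaries and
    hypothesis tests used to assess spindle alignment with the cell's long
    axis, seeded synthetic-data generators for every input, and a pipeline
    that turns per-cell records into deviation tables and statistical reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
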
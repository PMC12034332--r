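Package: segqa
Title: Screening Quality Assurance for Updated Auto-Segmentation Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage geometric quality assurance for deep-learning
    auto-segmentation software updates in radiotherapy. Computes the Dice
    similarity coefficient, maximum surface Hausdorff distance, and mean
    distance to agreement between pre-update and post-update organ contours
    on a shared CT voxel grid, flags notably modified organs under strict
    (A) or standard (B) screening criteria, and re-evaluates flagged organs
    against expert ground-truth contours with paired Wilcoxon signed-rank
    tests. Includes a deterministic synthetic phantom cohort generator that
    reproduces the characteristic failure modes of segmentation updates
    (slice extension/truncation, isolated regions, carved overlaps), plus
    report writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
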
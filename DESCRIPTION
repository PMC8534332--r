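Package: sonomorph
Title: Morphology and Motion-Phase Analysis of Nerve Segmentation Masks
    from Dynamic Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-segmentation analysis of median-nerve dynamics in dynamic
    ultrasound. Computes moment-based morphology metrics (cross-sectional
    area, centroid, chain-code perimeter, circularity) from binary
    segmentation masks, resolves multi-region predictions to a single nerve
    mask by largest-area and confidence-score rules, splits metric traces
    into finger flexion/extension phases with duration histograms (D90/D50
    modal ranges) and pooled 30-point normalized temporal profiles, and
    scores predicted mask sequences against ground truth by per-frame and
    per-video intersection over union. Includes a synthetic generator of
    moving, deforming nerve mask sequences with known ground truth and
    configurable degradation (boundary jitter, distractor blobs, region
    splits, scored instance candidates) so every pipeline stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
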
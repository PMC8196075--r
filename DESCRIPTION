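Package: strugglescope
Title: Struggle-Bout Segmentation and Fiber-Photometry Transient Analysis
    for Restraint Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing active stress-coping ("struggle") behavior
    during rodent restraint together with simultaneously recorded
    fluorescence-sensor signals. Converts markerless pose-tracking output
    into per-frame speeds and adaptive mobile/immobile states, segments and
    types struggle bouts, processes two-channel fiber-photometry recordings
    (isosbestic regression, delta-F/F, adaptive iteratively reweighted
    penalized least-squares baseline estimation, session Z-scoring,
    threshold transient detection), aligns signals to bout onsets with
    baseline-window Z-scoring and AUC/peak metrics, and provides the
    inferential procedures used on the resulting tables (Pearson
    correlation with slope confidence intervals, Welch and paired t tests,
    exact binomial tests, and the Benjamini-Krieger-Yekutieli two-stage
    step-up false discovery rate procedure). A synthetic-data generator
    with full ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
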
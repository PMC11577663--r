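Package: chartdigitizer
Title: Digitization of Smartphone Photographs of Paper Anesthesia Charts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning smartphone photographs of handwritten paper
    anesthesia charts into structured records. Implements photometric
    normalization (morphological shadow removal), landmark-based planar
    homography dewarping, half-stride sliding-window tiling with
    intersection-over-union duplicate merging, and rule-based inference of
    blood-pressure time series (flip-trick systolic/diastolic separation,
    legend-anchored mmHg calibration, timestamp imputation), physiological
    indicator values (KMeans-silhouette observation clustering, plausibility
    filtering, regression imputation), and checkbox states. Learned detectors
    and digit classifiers sit behind pluggable contracts with deterministic
    fixture implementations, and a synthetic-chart generator provides exact
    ground truth so the whole pipeline is testable without protected clinical
    data or trained model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
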
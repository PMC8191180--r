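Package: qamskit
Title: Single-Marker Quantification (QAMS) for Multi-Analyte HPLC-DAD
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Develop and stress-test single-marker quantification (quantitative
    analysis of multiple components by a single marker, QAMS) for multi-analyte
    HPLC with diode-array detection, modelled on a five loop-diuretic assay
    (furosemide, torasemide, azosemide, bumetanide, etacrynic acid). Provides a
    deterministic chromatogram simulator with condition perturbation, baseline
    estimation, peak detection and integration, external-standard calibration
    with detection limits, relative correction factors and single-marker
    back-calculation, qualitative identification by relative retention time and
    (first-derivative) UV spectral similarity, and an ICH-style validation
    battery: linearity, precision, stability, spike recovery, robustness, and
    external-standard versus single-marker method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
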
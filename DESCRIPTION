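Package: sddmark
Title: Automated Lipid Marker Discovery for Subretinal Drusenoid Deposits in
    Imaging Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end workflow for discovering candidate molecular markers
    of subretinal drusenoid deposits (SDD) in centroided MALDI imaging mass
    spectrometry (IMS) data. Implements spectral preprocessing (internal-peak
    m/z alignment, ppm recalibration, geometric common mass axis, mean-spectrum
    peak picking, robust 5-95 percentile TIC normalization), label-mask creation
    from non-negative matrix factorization patterns with balanced negative
    sampling, gradient-boosted pixel classification, TreeSHAP-based marker
    ranking with spatial SHAP maps, and lipid adduct/isotope mass annotation.
    Includes a synthetic retina-phantom IMS generator with known ground truth
    so that every stage is testable without donor data, and processed-mode
    imzML input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    xgboost,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
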
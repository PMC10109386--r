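Package: anthoimg
Title: Image-Based Anthocyanin Phenotyping with Reflectance Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimate relative anthocyanin content of leaves and canopies from
    multispectral band images or ordinary RGB images. Computes the normalized
    difference anthocyanin index (NDAI) and five comparison indices (NARI, ARI,
    mACI, mARI, RGI) per pixel, with single-point gray-card exposure
    calibration, plant/background segmentation by intensity thresholding or
    red:blue ratio plus morphological cleanup, object-level index summaries,
    and regression-based evaluation of indices against measured anthocyanin
    concentrations. A synthetic-scene generator with a Beer-Lambert style
    pigment-to-reflectance forward model provides ground-truthed test imagery,
    and a command-line interface wires the stages into reproducible runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
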
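Package: phenofuse
Title: Multi-Sensor NDVI Time-Series Reconstruction, Phenology, and Crop Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building gap-filled seasonal NDVI time series from
    cloud-affected multi-sensor satellite imagery and classifying cropland
    from them. Includes Sentinel-2 SCL and Landsat QA_PIXEL cloud masking,
    truncated Fourier-series fitting of gapped per-pixel NDVI series with
    daily reconstruction over the growing season, weekly sliding-window
    compositing, harmonization of sensors with different native resolutions
    onto a common 60 m geographic grid by bilinear resampling, field-level
    phenology metrics (seasonal NDVI maximum and its day of year) with
    one-way ANOVA and Tukey HSD comparisons, and random-forest crop/fallow
    classification with grouped splits, stratified group cross-validation
    and confusion-matrix metrics. A calibrated synthetic scene generator
    provides multi-sensor, cloud-gapped test landscapes with known ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
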
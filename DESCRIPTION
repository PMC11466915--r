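Package: droughtphen
Title: Drought-Resistance Indicators from High-Throughput Phenotyping Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives five drought-resistance indicators (biomass penalty,
    soil moisture at wilting from monotone water-use-efficiency curves,
    soil moisture at leaf desiccation from a short-wave-infrared reflectance
    ratio, soil moisture at chlorosis from NDVI, and root/shoot ratio) from
    per-plant phenotyping time series collected under a stop-watering drought
    protocol, and runs the downstream analyses of such screens: descriptive
    statistics, Spearman correlation structure, heteroscedastic
    variance-component partitioning by subgenus, Ward/Manhattan clustering,
    unscaled principal component analysis, and redundancy analysis against
    site-of-origin climate with permutation inference. Ships a synthetic
    experiment generator with known ground truth, plus a simplified
    shoot/root image segmentation and pixel-to-area calibration for synthetic
    rasters, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils,
    grDevices,
    splines,
    tibble,
    rlang,
    yaml,
    pracma,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    vegan,
    nlme,
    jsonlite,
    withr
Config/testthat/edition: 3
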
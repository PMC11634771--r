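Package: foramshift
Title: Three-Dimensional Distribution Change in Planktonic Foraminifera
    Census Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how planktonic foraminifera redistribute in a warming,
    acidifying ocean from water-column census counts and surface-sediment
    assemblages. Harmonizes catches across sampling devices and mesh sizes
    with a size-normalized catch model, interpolates gridded temperature and
    calcite-saturation fields to sample points, and estimates latitudinal
    diversity gradients, poleward range-edge shifts, vertical habitat-depth
    shifts, decadal abundance trends, thermal-response clusters, and the
    emergence of sampled locations from present-day (temperature, calcite
    saturation) niche envelopes under scenario fields. Includes a synthetic
    survey generator with injected ground truth so every estimator can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
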
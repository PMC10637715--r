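Package: osryield
Title: UAV Multispectral Flower Mapping and Seed-Yield Estimation for Oilseed Rape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for UAV multispectral surveys of oilseed rape
    (Brassica napus): computes the normalized difference yellowness index
    (NDYI) from green and blue reflectance bands, delineates flowering canopy
    by deterministic ISODATA (iso-cluster) classification of the index raster,
    estimates seed yield from the flower-pixel fraction with a calibratable
    area-to-mass coefficient, derives canopy height models (DSM minus DTM)
    with per-stage height summaries, and validates estimates with Pearson
    correlation, RMSE and summary-statistics t-tests. Includes a synthetic
    scene generator with known ground truth so the full pipeline can be
    exercised and tested end-to-end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    ggplot2,
    jsonlite,
    rlang,
    generics,
    mgcv,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
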
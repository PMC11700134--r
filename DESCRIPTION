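Package: mangroveheight
Title: Calibrating InSAR Digital Elevation Models to Mangrove Canopy Height
    with Spaceborne Lidar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for turning 12 m interferometric SAR (InSAR)
    elevation tiles into mangrove canopy height maps calibrated against
    spaceborne lidar footprints. Provides vertical datum harmonisation and
    artifact replacement against a coarser reference DEM, SAR
    backscatter-persistence water masking, mangrove-extent and country
    (EEZ) rasterisation, pairing of 25 m lidar footprints (RH98) with DEM
    zonal statistics, a quality-filter cascade with binned 3-sigma outlier
    removal, category-weighted square-root height regression with a 70/30
    stratified split, percentile/polynomial-inflection mitigation of
    implausibly tall tiles, and validation statistics against held-out
    lidar and aggregated airborne canopy height models. Includes a
    synthetic scene generator so the full workflow is exercised end-to-end
    without any satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
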
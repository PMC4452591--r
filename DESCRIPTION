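Package: reefhab
Title: Diagnostic Modelling of Potential Coral-Reef Habitat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts potential coral-reef habitat from gridded environmental
    climatologies with a multi-resolution threshold-envelope model: a 1-degree
    environmental envelope (temperature, salinity, nitrate, phosphate,
    aragonite saturation state) combined with a 30-arcsecond light/depth
    criterion derived from surface irradiance and the diffuse attenuation
    coefficient. Includes a seawater carbonate-system solver for the aragonite
    saturation state from total alkalinity and dissolved inorganic carbon,
    an inverse mode that derives environmental tolerance limits from observed
    reef locations, ROC-based optimization of the minimum-light parameter,
    spherical grid-area accounting, netCDF raster input/output, and a
    synthetic-world generator with planted ground truth for end-to-end
    testing without external data archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
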
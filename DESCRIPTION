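Package: xrrfit
Title: Slab-Model X-Ray Reflectivity and Isotherm Analysis for Lipid
    Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and constrained weighted least-squares
    fitting of specular X-ray reflectivity from Langmuir monolayers at the
    air-water interface, using two- and three-slab electron-density models
    with error-function interface smearing and Nevot-Croce roughness
    damping. Includes electron-counting estimation of lipid headgroup
    hydration, capillary-wave roughness prediction, empirical
    pressure-area compression-law fitting with Volta-potential slope
    analysis, and seeded synthetic-data generators so that every stage of
    the analysis chain can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
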
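Package: canopynorm
Title: Normalisation and Analysis of Canopy Temperatures from Overlapping
    Thermal Images of Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for high-throughput thermal phenotyping of replicated
    field trials imaged with an infrared camera. Plot canopy temperatures
    recorded in overlapping images are normalised against per-image means
    to remove environmental drift (cloud cover, irradiance, wind), and
    genotype means are estimated both by image-mean differencing and by an
    additive genotype-plus-image least-squares model. Includes generation
    of resolvable incomplete-block (alpha-type) trial layouts, a synthetic
    field-trial and image-acquisition simulator for method validation,
    pixel-level plot-temperature extraction with automated histogram
    quality control, Monte-Carlo randomisation tests with apparent least
    significant differences, rank-consistency analyses, and forward
    stepwise regression of yield on canopy temperature and agronomic
    covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
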
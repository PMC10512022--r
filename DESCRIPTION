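Package: goatpheno
Title: Digital Phenotype Extraction for Goats from Calibrated Field Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts body measurements and health phenotypes of goats from a
    fixed protocol of posed field photographs taken against a blue backdrop and
    ground tarp. The package segments the animal by chroma-key classification,
    refines the silhouette boundary by gradient snapping, detects a
    black-bordered calibration sign carrying pure red/green/blue color blocks
    to derive a centimeters-per-pixel scale and an affine color correction,
    and measures height at withers, body length, chest depth and width, and an
    elliptical-model chest girth. Close-up views yield a five-category FAMACHA
    conjunctiva anemia score and a tooth-eruption age class; the unobscured
    side view yields calibrated coat color clusters and a coat pattern map.
    A deterministic synthetic-scene generator with exact ground truth supports
    validation of every stage without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jpeg,
    yaml,
    xml2,
    zip,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite,
    optparse
Config/testthat/edition: 3
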
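Package: petquant
Title: Automated Reference-Region Quantification for Dynamic Brain PET
Version: 0.1.0
Authors@R:
    person("Turku", "Phantom", email = "petquant@example.org", role = c("aut", "cre"))
Description: Quantification core for dynamic brain positron emission tomography:
    automatic reference-region generation from anatomical parcellations
    (label extraction, anatomical correction, radioactivity tail exclusion),
    time-activity-curve extraction and SUV conversion, reference-tissue and
    plasma-input kinetic models (SRTM including a voxelwise basis-function
    variant, Logan and Patlak graphical analyses, SUVR, FUR, regional 2TCM),
    operator-variability evaluation statistics (spatial overlap, crossed
    random-effects ICC, distribution descriptors and overlap, relative bias),
    and a ground-truth 4D phantom simulator used as the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    lme4
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
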
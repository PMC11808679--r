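Package: aquarisk
Title: Multi-Index Groundwater Quality, Contamination and Health Risk Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing drinking-water quality from per-station
    water-chemistry tables: contamination indices (contamination factor,
    total/modified contamination index, pollution load index, Nemerow
    pollution index, metal pollution index, weighted contamination index),
    Hakanson-style potential ecological risk, USEPA-framework
    noncarcinogenic and carcinogenic health risk for child and adult
    cohorts, a weighted-arithmetic water quality index, guideline
    compliance accounting against WHO/USEPA/Indian/Bangladeshi standards,
    supporting multivariate statistics (correlation, PCA, Ward
    clustering) and inverse-distance-weighted spatial interpolation, plus
    a synthetic-data generator emulating coastal groundwater chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
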
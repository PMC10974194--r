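Package: thermowheat
Title: Passive Thermography Indices for Wheat Canopy Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for proximal infrared thermography of wheat
    field trials. Segments thermal frames into wheat and soil pixels by
    bimodal temperature-histogram thresholding (mean-of-peaks with an Otsu
    fallback), computes the soil-normalised Wheat Stress Index (WSI) and the
    Wheat Cover Index (WCI), aggregates them over phenological stages and
    varieties, and correlates the indices with yield components via linear
    fits, Pearson correlation and two-tailed t-tests (with a permutation
    cross-check). Includes a seeded synthetic thermal-field generator that
    emulates the two-species, nine-variety, four-stage study design with
    ground-truth masks, plus the study's published summary tables as
    packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
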
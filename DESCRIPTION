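Package: floravail
Title: Diet-Weighted Floral Resource Availability and Landscape Models of
    Crop Pollination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a pollinator-diet-weighted floral resource availability
    index (fai) per landscape and flowering period from plant-cover maps, and
    implements the comparative statistical workflow relating crop pollination
    success (broad bean seed set) to floral-resource maps versus land-cover
    maps: two-standard-deviation predictor standardization, ordinary least
    squares, AICc all-subsets model selection with delta < 2 retention and
    Akaike weights, contribution decompositions of the index by plant group,
    and landscape-composition regressions. Includes a synthetic landscape
    generator with the statistical structure of a 24-landscape pollination
    study, so the whole chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
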
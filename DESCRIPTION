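Package: esval
Title: Benefit-Transfer Ecosystem Service Valuation for Land-Cover Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Values the ecosystem services of a categorical land-cover map by
    the benefit-transfer method: per-class area accounting, assembly of adjusted
    per-hectare service coefficients across the four Millennium Ecosystem
    Assessment categories, carbon-sequestration valuation through the social
    cost of carbon, coffee net-present-value pricing, total ecosystem service
    value (ESV) computation, and coefficient-of-sensitivity elasticity analysis.
    Includes thematic-map accuracy assessment (overall accuracy, Cohen's kappa,
    producer's and user's accuracy), NDVI computation and per-class statistics,
    and a seeded synthetic-landscape generator (multinomial land cover, paired
    NIR/red reflectance bands, reference points with a prescribed confusion
    structure) so the full pipeline is testable without satellite imagery.
    Ships the per-hectare coefficient, carbon-stock and area tables for the
    Bench-Sheko zone (southwestern Ethiopia) as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
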
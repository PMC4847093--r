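Package: cspascore
Title: Toxicological Prioritization of Children's Safe Product Act Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scoring engine for the toxicological prioritization of chemicals
    reported under Washington State's Children's Safe Product Act (CSPA).
    Combines product attributes (target lifestage, exposure duration, skin
    application, concentration bin, exposure routes) and chemical attributes
    (solubility, vapor pressure, dermal permeability, observed absorption,
    endpoint certainty and potency) into an exposure score, a four-endpoint
    toxicity score, a total priority index and endpoint-specific priority
    scores. Includes the bundled chemical-score fixture for the 21 most
    frequently reported CSPA chemicals, aggregation and ranking utilities,
    quadrant classification, principal component analysis of score drivers,
    rank-concordance comparison against external prioritization schemes, and
    a seeded generator of CSPA-like synthetic report databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
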
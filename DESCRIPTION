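Package: phytotea
Title: Techno-Economic Modelling of Plant-Based Antimicrobial Protein Manufacturing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch flowsheet mass balances, facility scheduling, and cost
    accounting for plant molecular farming of antimicrobial proteins (AMPs)
    used as food processing aids. Models a transgenic, ethanol-inducible
    indoor Nicotiana benthamiana facility from seeding through spray-dried
    formulation: per-batch stream propagation through an extraction,
    filtration, chromatography and formulation train; translation of annual
    demand into biomass, plant, tray, seed and nutrient requirements;
    staggered-batch scheduling; CAPEX/OPEX/COGS rollups with
    upstream/downstream attribution; purchase-price sensitivity, expression
    level and production capacity scans; alternative-host scenarios (spinach,
    field-grown tobacco); and cost-of-use estimates for food safety
    applications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
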
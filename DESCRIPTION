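Package: nitropath
Title: Stoichiometry, Mass-Balance Apportionment and Cycle Simulation for
    Anammox-Based Nitrogen Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nitrogen transformation pathways in
    anammox-based biological nitrogen removal processes. Provides a
    stoichiometric engine that balances and combines nitrogen-cycle
    half-reactions (partial nitritation, complete nitrification, anammox,
    partial and complete heterotrophic denitrification), solves the closure
    weights that define complete-removal process configurations, and computes
    theoretical oxygen and organic (COD) demands per unit nitrogen; cycle
    mass-balance calculations that apportion nitrogen removal in a sequencing
    batch reactor (SBR) cycle between the anammox, nitrification and
    denitrification pathways; batch-test statistics such as the
    nitrate-to-nitrite transformation ratio; and a kinetic SBR cycle
    simulator with Monod rate laws that generates synthetic reactor
    campaigns with known ground-truth pathway fluxes for validating the
    mass-balance methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
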
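Package: gauss2sfca
Title: Gaussian Two-Step Floating Catchment Area Accessibility for
    Antivenom-Stocked Hospitals
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for road-network spatial accessibility of
    scarce hospital resources, built around the snakebite-antivenom use case:
    census-corrected gridded population demand surfaces, a travel-time road
    graph with class-specific speeds, origin-destination cost matrices,
    travel-time band reports per antivenom type, and Gaussian two-step
    floating catchment area (2SFCA) accessibility scores per bed and per
    health technician. Includes a fully synthetic province generator so every
    stage is testable without proprietary GIS inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
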
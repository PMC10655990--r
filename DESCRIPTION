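Package: standscape
Title: Stand-Resolution Simulation of Clear-Cut Forest Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic, annually iterated forest landscape model at the
    resolution of individual stands. Clear-cutting is modelled as a double
    question -- does the owner want to harvest this year, and is the cut
    legally allowed -- with harvest willingness driven by ownership and
    management intensity, and allowance by maturity ages, protection zoning
    and adjacency (total cutover area) rules evaluated sequentially within
    each simulation year. Includes a seeded synthetic landscape generator
    emulating the zoning, ownership and site structure of the hemiboreal
    Estonian forest estate, registry-refresh utilities (canopy-summary based
    clear-cut detection and composition imputation), named policy scenarios,
    and landscape output metrics: age-class composition, patch size
    distributions, edge proportions and incidence-function (Hanski)
    connectivity on a regular grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
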
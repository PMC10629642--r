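Package: agecouple
Title: Spatial Coupling of Population Aging and Elderly-Care Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the spatial supply-demand relationship
    between an older-adult population and city-level elderly-care
    resources.  Provides demand-side metrics (aging coefficient with
    stage classification, old-age dependence rate, older-adult
    agglomeration degree with density classes), Getis-Ord Gi* hot/cold
    spot statistics on binary contiguity weights with analytic z-scores
    and conditional permutation inference, grey relational coupling
    between a two-indicator demand system and a four-indicator supply
    system, per-resource coupling-coordination (spatial adaptation)
    matching, exact Fisher-Jenks natural-breaks classification, and a
    synthetic-region generator that emulates a nation of contiguous city
    units with spatially autocorrelated aging and tunably coupled
    resource levels.  The full pipeline is exposed both as composable
    functions and as a reproducible report runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
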
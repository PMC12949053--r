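Package: hydromap
Title: Phylogenetic Signal and Basin-Scale Mapping of Xylem Embolism Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify phylogenetic signal in xylem embolism resistance
    (the water potential at 50 percent loss of hydraulic conductivity, Psi50)
    across tree genera, compare the trait across taxonomic groupings, impute
    plot-level community-weighted Psi50 from forest-inventory composition via
    taxonomic gap-filling, and generalise plot values into regional patterns
    with geographically constrained Ward clustering, inverse-distance
    interpolation tuned by leave-one-out cross-validation, spatially
    constrained k-fold validation, and multivariate environmental similarity
    (MESS) extrapolation diagnostics. Includes a synthetic-data generator
    (Yule phylogenies with Brownian-motion traits of tunable signal strength,
    multi-site trait tables, spatially structured plot inventories and smooth
    environmental rasters) so the full chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    picante,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
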
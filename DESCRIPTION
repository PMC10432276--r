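Package: freshtrend
Title: Trend Analysis of Freshwater Invertebrate Community Time Series
Version: 0.1.0
Authors@R:
    person("freshtrend", "developers", email = "freshtrend@example.org",
           role = c("aut", "cre"))
Description: Tools for multidecadal analysis of freshwater invertebrate
    community time series: taxonomic diversity metrics (richness, abundance,
    Shannon diversity and evenness, individual-based rarefied richness,
    temporal turnover), fuzzy-coded trait processing with taxonomic
    gap-filling, distance-based functional diversity (convex-hull richness,
    evenness, divergence, Rao's quadratic entropy, redundancy), site-level
    trend estimation with AR(1) errors and metric-specific transforms,
    hierarchical meta-analysis of trends with study and country random
    effects, ten-year moving-window trajectory analysis, and shrinkage-prior
    regression of trends on environmental drivers. Includes a synthetic
    community generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
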
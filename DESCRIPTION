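Package: cladecensus
Title: Marker-Gene Census, Species-Discovery Curves and Clade-Size Laws
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying discoverable prokaryotic diversity from
    marker-gene cluster censuses. Builds sample-based rarefaction (species
    discovery) curves with hierarchical provenance stratification, estimates
    gene-cluster-to-species conversion factors by zero-intercept regression
    along logarithmic rarefactions, fits the marginal species-discovery power
    law S = k * N^-gamma and derives discovery coefficients alpha = 1 - gamma,
    computes relative evolutionary divergence (RED) on gene trees, calibrates
    taxonomy-free rank cutoffs by adjusted mutual information against
    reference labels under alternative rootings, and fits Willis power laws
    and Yule-Simon distributions to clade-size distributions. Includes a
    synthetic-data generator (species occurrence censuses, pure-birth trees
    with planted ranks, Simon preferential-attachment processes) with known
    ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
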
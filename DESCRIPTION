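Package: terpQSAR
Title: QSAR/QPAR Modelling of Essential-Oil Terpene Larvicides
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure- and property-larvicidal-activity
    modelling of essential-oil terpenes and terpenoids against Culex
    quinquefasciatus. Provides a hydrogen-depleted molecular-graph model with a
    SMILES parser, constitutional, topological (Balaban J, eccentricity,
    centric, Kier flexibility, E-state) and physicochemical (Moriguchi and
    Wildman-Crippen logP, molar refractivity, Ertl TPSA, hydrophilic factor)
    descriptors, Koopmans-theorem conceptual-DFT reactivity descriptors from
    frontier-orbital energies, maximum-likelihood probit dose-response fitting
    with Fieller confidence intervals for LC50 estimation, ordinary
    least-squares multiple regression with leave-one-out cross-validated Q2,
    genetic-algorithm descriptor-subset selection, and generators of synthetic
    bioassay and descriptor/activity data. Ships a curated 50-compound terpene
    library with experimental LC50 fixtures and transcribed descriptor tables
    for model reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
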
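Package: sfendotyper
Title: Endotype Discovery in Synovial-Fluid Proteomics
Version: 1.0.0
Authors@R:
    person("STEpUP", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for molecular endotype discovery in
    synovial-fluid aptamer proteomics. Generates synthetic cohorts with a
    controllable continuum-versus-cluster structure (dominant intracellular
    contamination factor, spin-status batch effects, planted endotypes,
    clinical covariate links); preprocesses abundance matrices (natural-log
    transform, median normalisation, empirical-Bayes batch adjustment,
    intracellular protein score computation and residualisation, per-protein
    standardisation); tests for significant clustering with the f(K)
    statistic and a majority-vote choice of cluster number; runs per-protein
    association scans with Benjamini-Hochberg FDR and discovery/replication
    calls; performs preranked signed running-sum set enrichment with
    permutation normalised enrichment scores; and estimates endotype
    detection power by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    MASS,
    cluster,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    uwot,
    optparse
Config/testthat/edition: 3
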
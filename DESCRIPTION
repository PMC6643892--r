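Package: ibdqtl
Title: IBD-Based QTL Mapping in Outcrossing Autopolyploids
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative trait locus
    (QTL) mapping in outcrossing autopolyploid F1 populations genotyped
    with dosage-scored SNP markers. Provides polysomic meiosis simulation
    (random bivalents or multivalents with double reduction), multipoint
    hidden-Markov estimation of identity-by-descent (IBD) probabilities
    under bivalent-only (noDR) and double-reduction-aware (DR) state
    spaces, per-homolog genotypic information coefficients (GIC),
    IBD-weighted regression QTL scans with permutation thresholds and
    LOD support intervals, BIC-based diagnosis of QTL configuration and
    mode of action, and a factorial power/precision study engine for
    synthetic phased maps.
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
    optparse
Config/testthat/edition: 3
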
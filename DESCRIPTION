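Package: habsize
Title: Multi-Scale Comparative Analysis of Body Size by Habitat Use in Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether body size differs consistently between
    salinity-defined habitat-use categories (marine, freshwater, brackish,
    marine-brackish, freshwater-brackish, euryhaline) across multiple scales
    of phylogenetic observation.  Provides readers for Newick trees and
    taxon tables, a seeded synthetic-data generator (birth-death trees,
    Mk-evolved habitat states, habitat-shifted Brownian body sizes), nine
    observation scales built by clade partitioning and transition hotspots,
    five size-difference metrics (log10 means, phylogenetic generalized
    least-squares means, Wilcoxon rank-sum tests, simulation-based
    phylogenetic ANOVA, PGLS ANOVA with residual randomization), Mk model
    fitting with stochastic character mapping of habitat transitions,
    majority and alignment summaries across clades, and a rule-based
    classifier of support for four suites of size-driving mechanisms
    (trophic level, migration, lineage age, species richness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
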
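Package: ilsq
Title: Coalescent Simulation, Quartet Concordance and Polyploidy Tests for
    Phylogenomic Discordance
Version: 1.0.0
Authors@R:
    person("ilsq", "developers", email = "ilsq-dev@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify gene-tree/species-tree discordance and test
    polyploidy hypotheses in phylogenomic datasets. Simulates gene trees
    under the multispecies coalescent within a species tree measured in
    coalescent units, estimates per-branch theta (the ratio of mutation-unit
    to coalescent-unit branch lengths, a proxy for the level of incomplete
    lineage sorting), tabulates quartet-topology frequencies and branch
    quartet supports (q1, q2, q3), compares empirical against simulated
    frequency tables by linear regression and by chi-square tests on minor
    topologies, classifies split support with a contraction rule, classifies
    copy-labeled collinear gene trees as supporting shared versus independent
    whole-genome duplications, fits Gaussian mixtures to Ks distributions by
    expectation-maximization, and dates LTR retrotransposon insertions with a
    molecular clock. A synthetic-data module generates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
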
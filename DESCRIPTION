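Package: hrtcst
Title: Community State Typing of Human Respiratory Tract Microbiome Profiles
Version: 0.1.0
Authors@R:
    person("HRT-CST", "Maintainers", email = "maintainers@hrtcst.org", role = c("aut", "cre"))
Description: Tools to identify Community State Types (CSTs) in human
    respiratory tract shotgun-metagenomic profiles. Implements hierarchical
    clustering of species-level relative-abundance tables with a Pearson
    correlation distance, silhouette-guided selection of the number of
    clusters, cluster retention filters and core-taxon characterization of
    the resulting CSTs; beta-diversity ordination (Bray-Curtis, PCoA,
    PERMANOVA), species richness, two-group and multi-group testing with
    Tukey HSD and Benjamini-Hochberg FDR; compartment-level prevalence,
    shared-species and abundance-gradient reports; Enzyme Commission (EC)
    class functional profiling with unique-pathway counting; and a
    synthetic-data generator that plants CST structure, compartment
    gradients, richness gaps and enzyme-class shifts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
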
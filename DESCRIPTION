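Package: plastiqtl
Title: Multi-Environment QTL Mapping and Phenotypic Plasticity for Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetics toolkit for genotype-by-environment (GxE) studies
    in biparental Saccharomyces cerevisiae crosses phenotyped under several
    fermentation conditions. Provides extraction of kinetic traits from cumulative
    CO2 release curves by local polynomial smoothing; plasticity statistics
    (rank-based inverse normal transform, two-way variance decompositions,
    broad-sense heritability from replicate variance, transgression rates,
    reaction-norm correlation distances and medoid clustering); multi-environment
    Haley-Knott regression scans with environment as additive and interactive
    covariate, genome-wide permutation thresholds, QTL calling with peak windows,
    kinetic-trait locus merging and cross colocalization; and a seeded synthetic
    cross generator (Haldane recombination, planted additive and GxE QTL effects,
    sigmoid fermentation curves) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
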
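Package: popgencor
Title: Simulation Study of Marker-Based Genetic Correlations Between Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-in-time Wright-Fisher simulation of two diverged
    populations with recombination and recurrent mutation, ascertainment of
    nested marker panels and causal loci under allele-frequency criteria,
    cross-population genomic relationship matrices, pedigree relationships,
    regression of genomic toward pedigree relationships, and bivariate
    average-information REML estimation of the additive genetic correlation
    between populations. Provides the building blocks and drivers to study
    when marker-based relationships yield unbiased estimates of the genetic
    correlation between two populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
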
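Package: milletpg
Title: Multilocus Population Genetics of the Foxtail Millet Domestication
    Bottleneck
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus sequence-diversity analysis of a crop and
    its wild progenitor: per-locus summary statistics (segregating sites,
    nucleotide diversity, Watterson's theta, Tajima's D, Fu and Li's D* and
    F*, haplotype statistics, four-gamete minimum recombination), population
    differentiation (Hudson's Fst, shared/fixed/private polymorphisms, the
    multilocus HKA test), Hill-Weir linkage-disequilibrium decay regression,
    a Hudson-style coalescent simulator with recombination for a
    split-with-bottleneck-and-migration demography, and rejection
    approximate Bayesian computation to estimate theta, rho/theta and the
    domestication bottleneck severity k = Nb/d, with a posterior-predictive
    scan for loci under selection. Includes a fully parameterised synthetic
    sequence-panel generator so every stage is testable without the original
    Sanger alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
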
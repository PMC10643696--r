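Package: breedsel
Title: Genomic Relatedness, Inbreeding and Breeder Selection for
    Conservation Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genome-wide SNP analysis pipeline for selecting breeders in
    conservation programs of small captive populations. Reads multi-sample
    VCF genotypes, applies variant and sample quality control (missingness,
    minor allele frequency, Hardy-Weinberg exact test), prunes markers by
    linkage disequilibrium, and computes per-individual heterozygosity and
    method-of-moments genomic inbreeding coefficients. Estimates pairwise
    identity-by-descent relatedness (Z0/Z1/Z2, Pi-Hat) with relationship-class
    thresholds, detects runs of homozygosity by sliding windows with F_ROH and
    generation dating of autozygous tracts, fits an admixture model by EM with
    cross-validation choice of the number of clusters and genetic-purity
    classification, and turns the results into ranked breeder-pair
    recommendations. A gene-dropping pedigree simulator with tracked founder
    alleles supplies ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
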
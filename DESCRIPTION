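Package: herdgen
Title: Conservation Genomics of Small Livestock Herds from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for SNP-array conservation genetics of
    small livestock populations: PLINK-style PED/MAP genotype input, sample
    and marker quality control (duplicate detection by identity-by-state
    similarity, minor-allele-frequency, Hardy-Weinberg exact test, call-rate
    and chromosome-class filters), per-marker and cohort genetic-diversity
    statistics, linkage-disequilibrium-based effective population size,
    runs-of-homozygosity detection with the genomic inbreeding coefficient
    F_ROH, VanRaden genomic relationship and identity-by-state distance
    matrices, principal component analysis, neighbor-joining clustering, and
    rule-based construction of conservation families from genomic kinship.
    Includes a pedigree-structured cohort simulator with known ground truth
    and a forward Wright-Fisher simulator for validating the effective
    population size estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
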
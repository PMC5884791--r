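Package: sexlinkit
Title: Mapping and Characterising Sex-Determination Loci in Atlantic Salmon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for locating and characterising the
    male-heterogametic (XX/XY) sex-determination loci of Atlantic salmon
    (Salmo salar): variant quality control including double-haploid artifact
    removal and array concordance, population diversity and divergence
    (windowed nucleotide diversity, reference-allele-frequency correlation,
    Weir-Cockerham F_ST, distance PCA), case-control GWAS with
    homeolog-aware association-leakage classification, delineation of the
    male-specific region from read depth and mate-pair architecture,
    hemizygosity testing via B-allele frequency, and neighbor-joining
    analysis of male-specific-region haplotypes with bootstrap support and
    outgroup-based ancestral assignment. A synthetic-data generator
    reproduces the statistical structure the analyses assume (hierarchical
    population structure, residually tetrasomic homeolog blocks, three
    segregating sdY lineages, paired-end alignment architecture around the
    male-specific-region junction) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
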